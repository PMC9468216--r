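# Minimal discrete-factor algebra used by the exact-inference engine.
# A factor is a list(vars, card, val): `vars` names the scope, `card` the
# per-variable category counts, and `val` a non-negative vector over the
# joint configurations with the FIRST variable varying fastest.

f_new <- function(vars, card, val) {
  stopifnot(length(vars) == length(card), length(val) == prod(card))
  list(vars = vars, card = as.integer(card), val = as.numeric(val))
}

# 0-based coordinate of variable at position `p` for every configuration of
# a grid with cardinalities `card`
grid_coord <- function(card, p) {
  n <- prod(card)
  lower <- if (p == 1) 1 else prod(card[seq_len(p - 1)])
  (seq_len(n) - 1) %/% lower %% card[p]
}

# linear indices into factor `f` for every configuration of the grid `w`
# (w must contain all of f's variables)
f_map_index <- function(f, w_vars, w_card) {
  n <- prod(w_card)
  idx <- rep(1, n)
  stride <- cumprod(c(1, f$card))[seq_along(f$card)]
  for (k in seq_along(f$vars)) {
    p <- match(f$vars[k], w_vars)
    idx <- idx + grid_coord(w_card, p) * stride[k]
  }
  idx
}

f_product <- function(a, b) {
  vars <- union(a$vars, b$vars)
  card <- integer(length(vars))
  card[match(a$vars, vars)] <- a$card
  card[match(b$vars, vars)] <- b$card
  f_new(vars, card, a$val[f_map_index(a, vars, card)] * b$val[f_map_index(b, vars, card)])
}

f_sum_out <- function(f, var) {
  keep <- setdiff(f$vars, var)
  if (!length(keep)) {
    return(f_new(character(0), integer(0), sum(f$val)))
  }
  kcard <- f$card[match(keep, f$vars)]
  g <- f_new(keep, kcard, numeric(prod(kcard)))
  idx <- f_map_index(g, f$vars, f$card)
  g$val <- as.numeric(rowsum(f$val, idx)[, 1])
  g
}

# condition on var = its `code_index`-th category (1-based), dropping var
f_reduce <- function(f, var, code_index) {
  p <- match(var, f$vars)
  if (is.na(p)) return(f)
  keep_mask <- grid_coord(f$card, p) == (code_index - 1)
  f_new(f$vars[-p], f$card[-p], f$val[keep_mask])
}

f_normalize <- function(f) {
  s <- sum(f$val)
  if (s <= 0) stop_contract("factor has zero total mass", "mmdbn_zero_evidence_error")
  f$val <- f$val / s
  f
}
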