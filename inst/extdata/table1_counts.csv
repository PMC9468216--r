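variable,code,label,n_without_mmd,n_with_mmd
sex,1,Men,4507,4806
sex,2,Women,4622,5817
age,1,<55,2018,1466
age,2,55-65,3202,3334
age,3,65-75,2514,3719
age,4,>=75,1395,2104
physical_activity,1,Light,324,454
physical_activity,2,Moderate,2832,3605
physical_activity,3,Vigorous,5973,6564
education,1,<=Primary school,3744,4844
education,2,<=Middle school,4101,4554
education,3,<College,1200,1142
education,4,>=College,84,83
residence,1,Town,1709,1892
residence,2,Combination,640,788
residence,3,Village,6738,7898
residence,4,Special area,42,45
marital_status,1,Married,7977,8912
marital_status,2,Divorced,111,130
marital_status,3,Widowed,982,1522
marital_status,4,Never married,59,59
sleep_duration,1,<=5h,2408,3951
sleep_duration,2,5-6h,2082,2235
sleep_duration,3,6-7h,1754,1630
sleep_duration,4,7-8h,1957,1860
sleep_duration,5,>8h,928,947
nap,1,0min,3589,3992
nap,2,<=30min,1573,1910
nap,3,>30min,3967,4721
smoking,0,No,5315,6215
smoking,1,Yes,3814,4408
alcohol,0,No,5800,7310
alcohol,1,Yes,3329,3313
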