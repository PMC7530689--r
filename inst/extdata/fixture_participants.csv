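participant_id,age_group,marital_status,education,first_anal_sex_age_group,sex_role,partner_venue,n_regular_partners,n_casual_partners,sex_with_msw,sex_with_women,drug_use,other_stds
P1,<=25,Unmarried,University/college or above,19-25,Both,Internet/software/app,1,0,No,No,No,No
P2,26-40,Married,High school,<=18,Insertive only,Offline venues,0,1,No,Yes,No,No
P3,>=41,Unmarried,University/college or above,26-40,Receptive only,Internet/software/app,2,2,No,No,Yes,Yes
P4,26-40,,Junior high school or below,19-25,Both,Internet/software/app,0,0,No,No,No,No
P5,<=25,Unmarried,High school,<=18,Both,Internet/software/app,1,3 or above,Yes,No,Yes,No
P6,>=41,Divorced or widowed,University/college or above,>=41,Insertive only,Offline venues,3 or above,0,No,No,No,No
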