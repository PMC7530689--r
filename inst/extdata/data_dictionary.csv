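variable,level,is_reference
age_group,<=25,TRUE
age_group,26-40,FALSE
age_group,>=41,FALSE
marital_status,Married,TRUE
marital_status,Unmarried,FALSE
marital_status,Divorced or widowed,FALSE
education,Junior high school or below,TRUE
education,High school,FALSE
education,University/college or above,FALSE
first_anal_sex_age_group,<=18,TRUE
first_anal_sex_age_group,19-25,FALSE
first_anal_sex_age_group,26-40,FALSE
first_anal_sex_age_group,>=41,FALSE
sex_role,Insertive only,TRUE
sex_role,Receptive only,FALSE
sex_role,Both,FALSE
partner_venue,Offline venues,TRUE
partner_venue,Internet/software/app,FALSE
n_regular_partners,0,TRUE
n_regular_partners,1,FALSE
n_regular_partners,2,FALSE
n_regular_partners,3 or above,FALSE
n_casual_partners,0,TRUE
n_casual_partners,1,FALSE
n_casual_partners,2,FALSE
n_casual_partners,3 or above,FALSE
sex_with_msw,No,TRUE
sex_with_msw,Yes,FALSE
sex_with_women,No,TRUE
sex_with_women,Yes,FALSE
drug_use,No,TRUE
drug_use,Yes,FALSE
other_stds,No,TRUE
other_stds,Yes,FALSE
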