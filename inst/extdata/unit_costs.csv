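category,basis,rate,duration_hours,component,price_year
gp,per_contact_hourly,136,0.28,primary_care,2015
practice_nurse,per_contact_hourly,44,0.26,primary_care,2015
community_nurse,per_contact_hourly,44,0.50,primary_care,2015
psychiatrist,per_contact_hourly,143,0.50,secondary_care,2015
psychologist,per_contact_hourly,98,1.00,secondary_care,2015
outpatient,per_unit,125,,secondary_care,2015
a_and_e,per_unit,138,,secondary_care,2015
social_worker,per_contact_hourly,55,0.50,social_care,2015
day_service,per_unit,40,,social_care,2015
medication,per_item,27.5,,medication,2015
residential_1_3bed,per_week,1496,,accommodation,2015
residential_4plusbed,per_week,1064,,accommodation,2015
supported_living_24h,per_week,872,,accommodation,2015
supported_living_lt24h,per_week,438,,accommodation,2015
floating_support,per_week,116,,accommodation,2015
informal_care,per_hour_weekly,24,,informal_care,2015
police_contact,per_unit,220,,criminal_justice,2015
court_appearance,per_unit,1200,,criminal_justice,2015
private_therapy,per_contact_hourly,98,1.00,out_of_pocket,2015
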