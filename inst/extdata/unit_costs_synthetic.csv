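category,unit_price_eur,unit
physician_contact,22.50,per contact
specialist_contact,35.00,per contact
psychological_contact,80.00,per contact
allied_health_contact,25.00,per contact
inpatient_day,550.00,per day
semiresidential_day,250.00,per day
rehabilitation_day,120.00,per day
car_km,0.30,per km
opportunity_hour,23.10,per hour
informal_care_hour,18.33,per hour
intervention,299.00,per participant
price_index_factor,1.04,index 2010 to 2013
ppp_eur_usd,1.29,USD per EUR
statutory_share,0.888,proportion statutorily insured
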