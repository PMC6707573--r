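"column","type","required","min","max","description"
"id","character",TRUE,,,"participant identifier"
"arm","character",TRUE,,,"trial arm: ISMI (intervention) or WLC (waitlist)"
"pss_t1","numeric",TRUE,0,40,"PSS-10 at baseline (week 0), integer"
"pss_t2","numeric",TRUE,0,40,"PSS-10 post-treatment (week 7), integer"
"pss_t3","numeric",TRUE,0,40,"PSS-10 at 6-month follow-up (week 26), integer"
"sf6d_t1","numeric",TRUE,0,1,"SF-6D utility at T1"
"sf6d_t2","numeric",TRUE,0,1,"SF-6D utility at T2"
"sf6d_t3","numeric",TRUE,0,1,"SF-6D utility at T3"
"eq5d_t1","numeric",TRUE,-0.6,1,"EQ-5D-3L utility at T1 (may be negative)"
"eq5d_t2","numeric",TRUE,-0.6,1,"EQ-5D-3L utility at T2"
"eq5d_t3","numeric",TRUE,-0.6,1,"EQ-5D-3L utility at T3"
"wage_month","numeric",TRUE,0,Inf,"gross monthly wage, EUR"
"physician_contacts_w1","numeric",TRUE,0,Inf,"GP contacts in window"
"specialist_contacts_w1","numeric",TRUE,0,Inf,"medical specialist contacts"
"psychological_contacts_w1","numeric",TRUE,0,Inf,"psychiatrist/psychotherapist contacts"
"allied_contacts_w1","numeric",TRUE,0,Inf,"allied-health contacts (physio, massage, OT)"
"inpatient_days_w1","numeric",TRUE,0,92,"hospital inpatient days"
"semiresidential_days_w1","numeric",TRUE,0,Inf,"semiresidential care days"
"rehabilitation_days_w1","numeric",TRUE,0,Inf,"rehabilitation days"
"rx_items_w1","character",TRUE,,,"prescriptions as 'drug:packages;...' or empty"
"otc_eur_w1","numeric",TRUE,0,Inf,"out-of-pocket OTC spend, EUR"
"car_km_w1","numeric",TRUE,0,Inf,"round-trip car km to services"
"public_transport_eur_w1","numeric",TRUE,0,Inf,"bus/taxi fares, EUR"
"waiting_hours_w1","numeric",TRUE,0,Inf,"waiting/treatment hours"
"informal_care_hours_w1","numeric",TRUE,0,Inf,"informal care / domestic help hours"
"absence_days_w1","numeric",TRUE,0,Inf,"work-loss days"
"impaired_days_w1","numeric",TRUE,0,Inf,"reduced-efficiency workdays"
"inefficiency_w1","numeric",TRUE,0,1,"inefficiency score in [0,1]"
"physician_contacts_w3","numeric",TRUE,0,Inf,"GP contacts in window"
"specialist_contacts_w3","numeric",TRUE,0,Inf,"medical specialist contacts"
"psychological_contacts_w3","numeric",TRUE,0,Inf,"psychiatrist/psychotherapist contacts"
"allied_contacts_w3","numeric",TRUE,0,Inf,"allied-health contacts (physio, massage, OT)"
"inpatient_days_w3","numeric",TRUE,0,92,"hospital inpatient days"
"semiresidential_days_w3","numeric",TRUE,0,Inf,"semiresidential care days"
"rehabilitation_days_w3","numeric",TRUE,0,Inf,"rehabilitation days"
"rx_items_w3","character",TRUE,,,"prescriptions as 'drug:packages;...' or empty"
"otc_eur_w3","numeric",TRUE,0,Inf,"out-of-pocket OTC spend, EUR"
"car_km_w3","numeric",TRUE,0,Inf,"round-trip car km to services"
"public_transport_eur_w3","numeric",TRUE,0,Inf,"bus/taxi fares, EUR"
"waiting_hours_w3","numeric",TRUE,0,Inf,"waiting/treatment hours"
"informal_care_hours_w3","numeric",TRUE,0,Inf,"informal care / domestic help hours"
"absence_days_w3","numeric",TRUE,0,Inf,"work-loss days"
"impaired_days_w3","numeric",TRUE,0,Inf,"reduced-efficiency workdays"
"inefficiency_w3","numeric",TRUE,0,1,"inefficiency score in [0,1]"
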