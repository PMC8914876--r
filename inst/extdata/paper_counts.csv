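item,value
subjects_total,5374
casualties_total,2940
collisions_total,2065
tbi_total,595
tbi_moderate_severe,315
tbi_mild_probable,133
tbi_symptomatic_possible,145
sah_total,171
focal_total,168
skull_fracture_total,179
sdh_total,96
dai_total,26
edh_total,16
n_pedestrian,144
n_cyclist,112
n_motorcyclist,267
n_car_occupant,3992
n_van_occupant,369
n_hgv_occupant,262
modsev_pedestrian,52
modsev_cyclist,29
modsev_motorcyclist,46
modsev_car_occupant,166
modsev_van_occupant,15
modsev_hgv_occupant,7
skull_fracture_pedestrian,34
helmeted_n,46
nonhelmeted_n,48
helmeted_skull_fracture,2
nonhelmeted_skull_fracture,12
helmeted_sdh,0
nonhelmeted_sdh,8
national_casualties,1190717
national_fatalities,12881
national_casualties_75mo,1102567
national_serious_75mo,152788
national_slight_75mo,951923
period_years,6.75
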