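# Editable column-map profile: canonical field -> source variable name.
# DHS variable codes differ between releases; adjust this file to match
# the export you are reading (values below follow the standard DHS recode
# names used by the 2008 Egypt children's file).
child_id: CASEID
diarrhoea: H11
fever: H22
cough: H31
child_age_months: HW1
sex: B4
maternal_age_first_birth_years: V212
bmi: V445
residence: V025
household_size: V136
antenatal_visits: M14
place_of_delivery: M15
working_status: V714
wealth_quintile: V190
mother_education: V106
region_id: SGOVERN
area7: V024
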