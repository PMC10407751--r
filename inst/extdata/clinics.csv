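clinic_id,name,n_doctors,n_nurses,consultations_per_hour,hours_per_shift,consultation_fee_sar,operation_cost_per_slot_sar,overbooking_cost_per_patient_sar
1,Endocrinology and Diabetes,3,6,2,6,300,35,70
2,Obstetrics and Gynecology,4,8,2,6,400,35,100
3,Neurology,3,6,2,6,500,35,100
4,Psychiatry,4,8,2,6,500,35,50
5,Orthopedics,3,6,2,6,500,35,50
6,Oncology,3,6,2,6,400,35,150
7,Ophthalmology,3,6,2,6,350,35,100
8,General Surgery,6,12,2,6,500,35,200
9,Cardiology,3,6,2,6,450,35,100
10,Family Medicine,4,8,2,6,200,35,140
11,Dermatology,5,10,2,6,550,35,50
12,Internal Medicine,5,9,2,6,400,35,70
13,Pediatrics,3,6,2,6,300,35,150
14,Pulmonology,3,6,2,6,500,35,250
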