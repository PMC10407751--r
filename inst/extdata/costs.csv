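line_item,sar_per_year
utilities,150000
government_fees,120000
space_rent,500000
doctor_salaries,6045572
nurse_salaries,5556747
admin_salaries,2511200
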