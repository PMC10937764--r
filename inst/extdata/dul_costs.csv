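item,code,descriptor,unit_cost_gbp
emergency_stenting,LB09D,"Non-Elective Intermediate Endoscopic Ureter Procedures, 19 years and over",1850.90
elective_ureteroscopy,LB65C-LB65E,"Elective Inpatient Major Endoscopic, Kidney or Ureter Procedures, 19 years and over",2854.44
stent_removal,LB09D,"Intermediate Ureter Procedures, 19 years and over",171.42
ultrasound,RD40Z-RD42Z,Ultrasound Scan without Contrast,65.54
ct_scan,RD23Z,"Computerised Tomography Scan of Two Areas, without Contrast",123.90
plain_film,PF,Plain Film,33.61
cystoscopy,LB72A,"Diagnostic Cystoscopy, 19 years and over",171.38
pcnl_cc2plus,LB75A,Percutaneous Nephrolithotomy with CC score 2+,7202.79
pcnl_cc01,LB75B,Percutaneous Nephrolithotomy with CC score 0-1,2546.12
followup_attendance,WF02C,"Multi-professional Non-Admitted Non-Face-to-Face Attendance, Follow-up",77.56
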