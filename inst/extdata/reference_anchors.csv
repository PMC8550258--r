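source,analyte,period,time,value
dallmann,albumin,pregnancy,20,38.2
dallmann,albumin,pregnancy,37,34.7
abduljalil,albumin,pregnancy,20,40.9
abduljalil,albumin,pregnancy,37,34.7
dallmann,aag,pregnancy,24,61.2
dallmann,aag,pregnancy,37,59.5
abduljalil,aag,pregnancy,24,58.6
abduljalil,aag,pregnancy,37,55.3
dallmann,albumin,postpartum,0,30.8
dallmann,albumin,postpartum,4,41.9
dallmann,albumin,postpartum,7,46.4
dallmann,aag,postpartum,2,126.1
dallmann,aag,postpartum,7,70.1
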