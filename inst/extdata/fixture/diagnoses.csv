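patient_id,date,code,setting
P01,2011-06-01,I48.0,outpatient
P02,2011-05-01,I48.1,outpatient
P02,2012-04-10,I63.9,inpatient
P03,2011-04-01,I48.0,outpatient
P03,2012-04-10,I63.0,emergency
P04,2010-02-01,I48.2,outpatient
P05,2009-05-01,I48.0,outpatient
P06,2012-01-05,I48.0,outpatient
P07,2011-09-01,I48.0,outpatient
P07,2012-03-01,C50.1,inpatient
P08,2012-01-01,I48.0,outpatient
P10,2011-12-01,I48.0,outpatient
P10,2012-01-10,I63.5,inpatient
P11,2013-06-01,I48.0,outpatient
P12,2011-01-01,I48.0,outpatient
P13,2012-06-15,I48.3,outpatient
P13,2013-07-20,I63.2,inpatient
P14,2012-07-01,I48.0,outpatient
P14,2013-07-01,I61.0,emergency
P15,2012-08-01,I48.1,outpatient
P15,2013-12-26,I61.1,inpatient
P16,2013-01-05,I48.0,outpatient
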