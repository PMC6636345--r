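patient_id,drug_code,start_date,days_supplied
P01,WARF,2012-01-01,90
P02,DABI,2012-01-01,800
P03,RIVA,2012-01-01,30
P03,RIVA,2012-03-02,30
P04,WARF,2012-01-01,30
P04,WARF,2012-03-01,30
P05,WARF,2009-06-01,30
P05,WARF,2010-03-01,90
P06,WARF,2012-07-01,30
P06,DABI,2012-07-01,30
P07,WARF,2012-08-01,90
P08,WARF,2012-05-01,90
P09,DABI,2012-09-01,90
P10,RIVA,2012-05-01,800
P11,WARF,2014-06-01,800
P13,WARF,2013-01-01,800
P14,APIX,2013-02-01,800
P15,WARF,2013-03-01,800
P16,DABI,2014-01-01,800
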