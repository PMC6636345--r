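patient_id,birth_date,sex,data_end_date
P01,1950-01-01,male,2016-12-31
P02,1945-03-02,female,2016-12-31
P03,1940-05-05,male,2016-12-31
P04,1938-07-07,female,2016-12-31
P05,1942-02-02,male,2016-12-31
P06,1949-03-03,female,2016-12-31
P07,1955-05-05,male,2016-12-31
P08,1993-06-01,female,2016-12-31
P09,1948-01-01,male,2016-12-31
P10,1950-12-12,female,2016-12-31
P11,1944-09-09,male,2015-06-01
P12,1951-01-01,female,2016-12-31
P13,1947-08-09,male,2016-12-31
P14,1952-02-02,female,2016-12-31
P15,1939-11-11,male,2016-12-31
P16,1960-04-04,female,2016-12-31
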