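label,n_in,n_dropped,n_out
all patients,16,0,16
exposure prescription within study window,16,1,15
no exposure prescription within 365 days before index,15,1,14
single exposure group on index date,14,1,13
AF diagnosis before index,13,1,12
aged at least 20 at index,12,1,11
no cancer within 1 year before index,11,1,10
incident subcohort: stroke,10,1,9
incident subcohort: ich,10,0,10
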