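patient_id,group,outcome,mode,time_days,event,end_reason
P01,warfarin,ich,AT,90,0,discontinuation
P02,noac,ich,AT,730,0,max_followup
P03,noac,ich,AT,30,0,discontinuation
P04,warfarin,ich,AT,90,0,discontinuation
P10,noac,ich,AT,730,0,max_followup
P11,warfarin,ich,AT,365,0,data_end
P13,warfarin,ich,AT,730,0,max_followup
P14,noac,ich,AT,150,1,outcome
P15,warfarin,ich,AT,300,1,outcome
P16,noac,ich,AT,730,0,max_followup
P01,warfarin,ich,ITT,730,0,max_followup
P02,noac,ich,ITT,730,0,max_followup
P03,noac,ich,ITT,730,0,max_followup
P04,warfarin,ich,ITT,730,0,max_followup
P10,noac,ich,ITT,730,0,max_followup
P11,warfarin,ich,ITT,365,0,data_end
P13,warfarin,ich,ITT,730,0,max_followup
P14,noac,ich,ITT,150,1,outcome
P15,warfarin,ich,ITT,300,1,outcome
P16,noac,ich,ITT,730,0,max_followup
P01,warfarin,stroke,AT,90,0,discontinuation
P02,noac,stroke,AT,100,1,outcome
P03,noac,stroke,AT,30,0,discontinuation
P04,warfarin,stroke,AT,90,0,discontinuation
P11,warfarin,stroke,AT,365,0,data_end
P13,warfarin,stroke,AT,200,1,outcome
P14,noac,stroke,AT,730,0,max_followup
P16,noac,stroke,AT,730,0,max_followup
P01,warfarin,stroke,ITT,730,0,max_followup
P02,noac,stroke,ITT,100,1,outcome
P03,noac,stroke,ITT,100,1,outcome
P04,warfarin,stroke,ITT,730,0,max_followup
P11,warfarin,stroke,ITT,365,0,data_end
P13,warfarin,stroke,ITT,200,1,outcome
P14,noac,stroke,ITT,730,0,max_followup
P16,noac,stroke,ITT,730,0,max_followup
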