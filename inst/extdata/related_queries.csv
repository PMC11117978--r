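drug,term
SEM,weight loss semaglutide
SEM,semaglutide for weight loss
SEM,ozempic weight loss
SEM,side effects semaglutide
LIR,liraglutide weight loss
LIR,liraglutide for weight loss
LIR,liraglutide side effects
TIR,tirzepatide weight loss
TIR,tirzepatide for weight loss
TIR,semaglutide weight loss
TIR,tirzepatide side effects
DUL,dulaglutide weight loss
DUL,dulaglutide side effects
EXE,exenatide weight loss
EXE,exenatide side effects
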