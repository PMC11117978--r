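pt,hlt,soc,observed
Dose calculation error,modified_dose,"Injury, poisoning and procedural complications",TRUE
Dose calculation error associated with device,modified_dose,"Injury, poisoning and procedural complications",FALSE
Drug dose titration not performed,modified_dose,"Injury, poisoning and procedural complications",TRUE
Drug titration error,modified_dose,"Injury, poisoning and procedural complications",TRUE
Incorrect dosage administered,modified_dose,"Injury, poisoning and procedural complications",TRUE
Incorrect dose administered,modified_dose,"Injury, poisoning and procedural complications",TRUE
Incorrect dose administered by device,modified_dose,"Injury, poisoning and procedural complications",TRUE
Incorrect dose administered by product,modified_dose,"Injury, poisoning and procedural complications",TRUE
Incorrect product dosage form administered,modified_dose,"Injury, poisoning and procedural complications",FALSE
Product dosage form confusion,modified_dose,"Injury, poisoning and procedural complications",FALSE
Wrong dose,modified_dose,"Injury, poisoning and procedural complications",TRUE
Accidental overdose,overdose,"Injury, poisoning and procedural complications",TRUE
Intentional overdose,overdose,"Injury, poisoning and procedural complications",TRUE
Extra dose administered,overdose,"Injury, poisoning and procedural complications",TRUE
Overdose,overdose,"Injury, poisoning and procedural complications",TRUE
Prescribed overdose,overdose,"Injury, poisoning and procedural complications",TRUE
Accidental underdose,underdose,"Injury, poisoning and procedural complications",TRUE
Drug dose omission by device,underdose,"Injury, poisoning and procedural complications",TRUE
Incomplete dose administered,underdose,"Injury, poisoning and procedural complications",FALSE
Intentional dose omission,underdose,"Injury, poisoning and procedural complications",TRUE
Intentional underdose,underdose,"Injury, poisoning and procedural complications",TRUE
Prescribed underdose,underdose,"Injury, poisoning and procedural complications",TRUE
Product dose omission,underdose,"Injury, poisoning and procedural complications",FALSE
Product dose omission in error,underdose,"Injury, poisoning and procedural complications",TRUE
Product dose omission issue,underdose,"Injury, poisoning and procedural complications",TRUE
Underdose,underdose,"Injury, poisoning and procedural complications",TRUE
Contraindicated product administered,off_label_use,Surgical and medical procedures,TRUE
Contraindicated product prescribed,off_label_use,Surgical and medical procedures,TRUE
Drug effective for unapproved indication,off_label_use,Surgical and medical procedures,FALSE
Off-label use,off_label_use,Surgical and medical procedures,TRUE
Off-label use of device,off_label_use,Surgical and medical procedures,TRUE
Product use in unapproved therapeutic environment,off_label_use,Surgical and medical procedures,FALSE
Product use in unapproved indication,off_label_use,Surgical and medical procedures,TRUE
Product used for unknown indication,off_label_use,Surgical and medical procedures,FALSE
Unintentional use for unapproved indication,off_label_use,Surgical and medical procedures,TRUE
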