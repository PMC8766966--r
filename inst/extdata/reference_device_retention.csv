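analyte,solvent_loss_pct,saliva_loss_pct
AML,-94,-97
TEL,-100,-62
DOX,-99,-100
NBV,-97,-98
HCTZ,-33.5,-54
ATE,-46.5,-21
SCB,-30,-14
RAM,-31,2
OLM,-1.5,2
CHL,-14,-30
CLN,-28.5,24
IDP,19.5,33
VAL,-13,-10
NFD,-13,-38
RAM-M,-12,13
SCB-M,-22.5,-2
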