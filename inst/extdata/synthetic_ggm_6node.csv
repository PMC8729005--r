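,ala,gly,ser,leu,val,ile
ala,1,0.52801742730662216,0.57387171406298865,-0.030003502126783155,-0.43354779873043298,0
gly,0.52801742730662216,1,0,0.072399295493960403,0,-0.1317558394744992
ser,0.57387171406298865,0,1,0,0.53600187906995422,0.48688575709238646
leu,-0.030003502126783155,0.072399295493960403,0,1,-0.50107493028044703,0
val,-0.43354779873043298,0,0.53600187906995422,-0.50107493028044703,1,0
ile,0,-0.1317558394744992,0.48688575709238646,0,0,1
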