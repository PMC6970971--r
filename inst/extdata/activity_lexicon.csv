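activity_name,caloric_value
watching,80
reading,90
walking,280
running,700
drinking,104
sitting,75
cooking,200
skiing,500
gym,440
playing,350
swimming,560
cycling,590
yoga,260
dancing,390
hiking,470
skating,480
jogging,560
weightlifting,250
basketball,630
hockey,640
soccer,600
tennis,570
golf,330
rowing,560
climbing,650
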