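source,age,outcome,arm,count
trial,NA,CV_deaths,active,161
trial,NA,CV_deaths,control,188
trial,NA,CV_deaths,incremental,-27
trial,NA,HHF,active,505
trial,NA,HHF,control,724
trial,NA,HHF,incremental,-219
trial,NA,UHFV,active,68
trial,NA,UHFV,control,129
trial,NA,UHFV,incremental,-61
model,72,CV_deaths,active,155
model,72,CV_deaths,control,179
model,72,CV_deaths,incremental,-22
model,72,HHF,active,571
model,72,HHF,control,842
model,72,HHF,incremental,-253
model,72,UHFV,active,63
model,72,UHFV,control,128
model,72,UHFV,incremental,-60
model,62,CV_deaths,active,155
model,62,CV_deaths,control,179
model,62,CV_deaths,incremental,-22
model,62,HHF,active,463
model,62,HHF,control,683
model,62,HHF,incremental,-205
model,62,UHFV,active,32
model,62,UHFV,control,64
model,62,UHFV,incremental,-30
model,82,CV_deaths,active,150
model,82,CV_deaths,control,173
model,82,CV_deaths,incremental,-23
model,82,HHF,active,679
model,82,HHF,control,1003
model,82,HHF,incremental,-303
model,82,UHFV,active,122
model,82,UHFV,control,246
model,82,UHFV,incremental,-116
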