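body_region,variable,level,count
head,total,total,68831
head,sex,F,29540
head,sex,M,39291
head,age_group,<1,5507
head,age_group,1-4,12428
head,age_group,5-9,13630
head,age_group,10-14,17779
head,age_group,15-21,19487
head,manufacturer,GE,27071
head,manufacturer,Siemens,31038
head,manufacturer,Philips,3964
head,manufacturer,Canon,6758
neck,total,total,11131
neck,sex,F,4851
neck,sex,M,6280
neck,age_group,<1,158
neck,age_group,1-4,1364
neck,age_group,5-9,1976
neck,age_group,10-14,3202
neck,age_group,15-21,4431
neck,manufacturer,GE,3664
neck,manufacturer,Siemens,5935
neck,manufacturer,Philips,608
neck,manufacturer,Canon,924
chest,total,total,11253
chest,sex,F,5146
chest,sex,M,6107
chest,age_group,<1,864
chest,age_group,1-4,1746
chest,age_group,5-9,1919
chest,age_group,10-14,2773
chest,age_group,15-21,3951
chest,manufacturer,GE,4294
chest,manufacturer,Siemens,6411
chest,manufacturer,Philips,169
chest,manufacturer,Canon,379
cardiac,total,total,524
cardiac,sex,F,199
cardiac,sex,M,325
cardiac,age_group,<1,256
cardiac,age_group,1-4,120
cardiac,age_group,5-9,49
cardiac,age_group,10-14,52
cardiac,age_group,15-21,47
cardiac,manufacturer,GE,59
cardiac,manufacturer,Siemens,456
cardiac,manufacturer,Philips,4
cardiac,manufacturer,Canon,5
abdomen_pelvis,total,total,29512
abdomen_pelvis,sex,F,15153
abdomen_pelvis,sex,M,14359
abdomen_pelvis,age_group,<1,345
abdomen_pelvis,age_group,1-4,2241
abdomen_pelvis,age_group,5-9,5440
abdomen_pelvis,age_group,10-14,8738
abdomen_pelvis,age_group,15-21,12748
abdomen_pelvis,manufacturer,GE,10590
abdomen_pelvis,manufacturer,Siemens,13913
abdomen_pelvis,manufacturer,Philips,1729
abdomen_pelvis,manufacturer,Canon,3280
chest_abdomen_pelvis,total,total,4229
chest_abdomen_pelvis,sex,F,1820
chest_abdomen_pelvis,sex,M,2409
chest_abdomen_pelvis,age_group,<1,80
chest_abdomen_pelvis,age_group,1-4,599
chest_abdomen_pelvis,age_group,5-9,743
chest_abdomen_pelvis,age_group,10-14,1041
chest_abdomen_pelvis,age_group,15-21,1766
chest_abdomen_pelvis,manufacturer,GE,2592
chest_abdomen_pelvis,manufacturer,Siemens,1498
chest_abdomen_pelvis,manufacturer,Philips,56
chest_abdomen_pelvis,manufacturer,Canon,83
spine,total,total,2917
spine,sex,F,1316
spine,sex,M,1601
spine,age_group,<1,3
spine,age_group,1-4,48
spine,age_group,5-9,213
spine,age_group,10-14,928
spine,age_group,15-21,1725
spine,manufacturer,GE,1170
spine,manufacturer,Siemens,1282
spine,manufacturer,Philips,350
spine,manufacturer,Canon,115
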