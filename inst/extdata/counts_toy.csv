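"site","occasion","species","count","strata","temp_site","su","sm","date_obs","temp_obs"
"site1",1,"spA",6,0,14.2,1,1,10,19.56
"site1",1,"spB",1,0,14.2,1,1,10,19.56
"site1",1,"spC",3,0,14.2,1,1,10,19.56
"site1",1,"spD",6,0,14.2,1,1,10,19.56
"site1",2,"spA",0,0,14.2,1,1,40,15.94
"site1",2,"spB",2,0,14.2,1,1,40,15.94
"site1",2,"spC",0,0,14.2,1,1,40,15.94
"site1",2,"spD",1,0,14.2,1,1,40,15.94
"site2",1,"spA",1,1,15.1,1,2,10,15.65
"site2",1,"spB",5,1,15.1,1,2,10,15.65
"site2",1,"spC",0,1,15.1,1,2,10,15.65
"site2",1,"spD",1,1,15.1,1,2,10,15.65
"site2",2,"spA",1,1,15.1,1,2,40,13.21
"site2",2,"spB",1,1,15.1,1,2,40,13.21
"site2",2,"spC",2,1,15.1,1,2,40,13.21
"site2",2,"spD",7,1,15.1,1,2,40,13.21
"site3",1,"spA",0,0,13.8,2,1,10,18.79
"site3",1,"spB",1,0,13.8,2,1,10,18.79
"site3",1,"spC",2,0,13.8,2,1,10,18.79
"site3",1,"spD",2,0,13.8,2,1,10,18.79
"site3",2,"spA",3,0,13.8,2,1,40,14.39
"site3",2,"spB",1,0,13.8,2,1,40,14.39
"site3",2,"spC",0,0,13.8,2,1,40,14.39
"site3",2,"spD",4,0,13.8,2,1,40,14.39
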