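# Packaged peak-force / activation / joint-reaction-force summary for the
# three shoulder configurations (NS natural, RSP reverse prosthesis, DBSP
# dual-bearing prosthesis) over four motions (ABD abduction, SCP scaption,
# IR internal rotation, ER external rotation). pct_change is the printed
# percent change relative to NS; one DBSP/SCP JRF percent cell is
# typographically corrupted in the source and carries asserted=FALSE.
model,motion,row,force_N,activation,pct_change,asserted
NS,ABD,anterior_deltoid,136.3,0.27,NA,TRUE
NS,ABD,middle_deltoid,292.4,0.25,NA,TRUE
NS,ABD,posterior_deltoid,330,0.2,NA,TRUE
NS,ABD,supraspinatus,56.1,0.09,NA,TRUE
NS,ABD,infraspinatus,95.4,0.07,NA,TRUE
NS,ABD,teres_minor,36.6,0.07,NA,TRUE
NS,ABD,subscapularis,213.6,0.15,NA,TRUE
RSP,ABD,anterior_deltoid,121.7,0.24,-11,TRUE
DBSP,ABD,anterior_deltoid,116.5,0.23,-15,TRUE
RSP,ABD,middle_deltoid,299.4,0.25,2,TRUE
DBSP,ABD,middle_deltoid,396.8,0.33,36,TRUE
RSP,ABD,posterior_deltoid,156.5,0.1,-53,TRUE
DBSP,ABD,posterior_deltoid,107.9,0.07,-67,TRUE
RSP,ABD,infraspinatus,152.7,0.11,60,TRUE
DBSP,ABD,infraspinatus,130.2,0.09,36,TRUE
RSP,ABD,teres_minor,118,0.24,222,TRUE
DBSP,ABD,teres_minor,68.9,0.14,88,TRUE
RSP,ABD,subscapularis,205,0.14,-4,TRUE
DBSP,ABD,subscapularis,58.6,0.04,-73,TRUE
NS,ABD,JRF,1054,NA,NA,TRUE
RSP,ABD,JRF,1142.2,NA,8,TRUE
DBSP,ABD,JRF,957.5,NA,-9,TRUE
NS,SCP,anterior_deltoid,126.7,0.25,NA,TRUE
NS,SCP,middle_deltoid,227.1,0.19,NA,TRUE
NS,SCP,posterior_deltoid,281.8,0.17,NA,TRUE
NS,SCP,supraspinatus,53.4,0.09,NA,TRUE
NS,SCP,infraspinatus,220.9,0.15,NA,TRUE
NS,SCP,teres_minor,38.6,0.08,NA,TRUE
NS,SCP,subscapularis,40.2,0.03,NA,TRUE
RSP,SCP,anterior_deltoid,143.3,0.28,13,TRUE
DBSP,SCP,anterior_deltoid,146.4,0.29,16,TRUE
RSP,SCP,middle_deltoid,265.5,0.22,17,TRUE
DBSP,SCP,middle_deltoid,370.4,0.31,63,TRUE
RSP,SCP,posterior_deltoid,195.2,0.12,-31,TRUE
DBSP,SCP,posterior_deltoid,137.2,0.08,-51,TRUE
RSP,SCP,infraspinatus,255.9,0.18,16,TRUE
DBSP,SCP,infraspinatus,259.5,0.18,17,TRUE
RSP,SCP,teres_minor,139.5,0.28,261,TRUE
DBSP,SCP,teres_minor,80.7,0.16,109,TRUE
RSP,SCP,subscapularis,19.8,0.01,-51,TRUE
DBSP,SCP,subscapularis,14.7,0.01,-63,TRUE
NS,SCP,JRF,1031.6,NA,NA,TRUE
RSP,SCP,JRF,1176.8,NA,14,TRUE
DBSP,SCP,JRF,1095.6,NA,6,FALSE
NS,IR,anterior_deltoid,110.2,0.22,NA,TRUE
NS,IR,middle_deltoid,187.4,0.16,NA,TRUE
NS,IR,posterior_deltoid,19.2,0.01,NA,TRUE
NS,IR,supraspinatus,50.2,0.08,NA,TRUE
NS,IR,infraspinatus,374.8,0.26,NA,TRUE
NS,IR,teres_minor,180.3,0.36,NA,TRUE
NS,IR,subscapularis,110.7,0.08,NA,TRUE
RSP,IR,anterior_deltoid,113.9,0.23,3,TRUE
DBSP,IR,anterior_deltoid,130.4,0.26,18,TRUE
RSP,IR,middle_deltoid,277.2,0.23,48,TRUE
DBSP,IR,middle_deltoid,307.4,0.26,64,TRUE
RSP,IR,posterior_deltoid,30.9,0.02,61,TRUE
DBSP,IR,posterior_deltoid,43.1,0.03,124,TRUE
RSP,IR,infraspinatus,338,0.24,-10,TRUE
DBSP,IR,infraspinatus,392.3,0.27,5,TRUE
RSP,IR,teres_minor,162.5,0.33,-10,TRUE
DBSP,IR,teres_minor,117.6,0.24,-35,TRUE
RSP,IR,subscapularis,19.9,0.01,-82,TRUE
DBSP,IR,subscapularis,14.5,0.01,-87,TRUE
NS,IR,JRF,827.6,NA,NA,TRUE
RSP,IR,JRF,935.9,NA,13,TRUE
DBSP,IR,JRF,946.3,NA,14,TRUE
NS,ER,anterior_deltoid,122.7,0.24,NA,TRUE
NS,ER,middle_deltoid,157.8,0.13,NA,TRUE
NS,ER,posterior_deltoid,17.9,0.01,NA,TRUE
NS,ER,supraspinatus,49.6,0.08,NA,TRUE
NS,ER,infraspinatus,369.3,0.26,NA,TRUE
NS,ER,teres_minor,171.3,0.34,NA,TRUE
NS,ER,subscapularis,111.6,0.08,NA,TRUE
RSP,ER,anterior_deltoid,112.4,0.22,-8,TRUE
DBSP,ER,anterior_deltoid,133.7,0.26,9,TRUE
RSP,ER,middle_deltoid,292.4,0.25,85,TRUE
DBSP,ER,middle_deltoid,309.9,0.26,96,TRUE
RSP,ER,posterior_deltoid,39,0.02,118,TRUE
DBSP,ER,posterior_deltoid,44.4,0.03,148,TRUE
RSP,ER,infraspinatus,329.3,0.23,-11,TRUE
DBSP,ER,infraspinatus,392.4,0.27,6,TRUE
RSP,ER,teres_minor,151.6,0.31,-12,TRUE
DBSP,ER,teres_minor,108.4,0.22,-37,TRUE
RSP,ER,subscapularis,16.2,0.01,-85,TRUE
DBSP,ER,subscapularis,14.6,0.01,-87,TRUE
NS,ER,JRF,779.5,NA,NA,TRUE
RSP,ER,JRF,935,NA,20,TRUE
DBSP,ER,JRF,982.5,NA,26,TRUE
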