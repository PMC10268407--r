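patient_id,group,dect,recist,ca125
D01,dect_pd,PD,PD,PD
D02,dect_pd,PD,PD,PD
D03,dect_pd,PD,PD,PD
D04,dect_pd,PD,PD,PD
D05,dect_pd,PD,SD,PD
D06,dect_pd,PD,SD,PD
D07,dect_pd,PD,SD,PD
D08,dect_pd,PD,SD,PD
D09,dect_pd,PD,SD,PD
D10,dect_pd,PD,SD,SD
D11,dect_pd,PD,SD,SD
R01,dect_pr,PR,PR,PR
R02,dect_pr,PR,PR,PR
R03,dect_pr,PR,PR,PR
R04,dect_pr,PR,PR,PR
R05,dect_pr,PR,PR,PR
R06,dect_pr,PR,SD,PR
R07,dect_pr,PR,SD,SD
R08,dect_pr,PR,SD,SD
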