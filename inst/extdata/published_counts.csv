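target_id,description,numerator,denominator
t1,stable disease by size criteria among evaluable patients,24,40
t2,partial response or progression by size criteria among evaluable patients,16,40
t6,size-criteria responders among relapse patients,25,32
t7,CA125-criteria responders among relapse patients,17,32
t8,iodine-criteria responders among relapse patients,22,32
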