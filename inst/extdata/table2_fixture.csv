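agent,n_trials,moa_class,goal,ndds
ATH-1017,1,dmt,Neuroprotection,PD|DLB
BIIB092,1,dmt,Tau extracellular transmission,FTLD|CBD|CTE
davunetide,1,dmt,Tau aggregation,PSP|CBD|FTLD
deferiprone,1,dmt,Oxidative stress,ALS|PD
insulin,1,dmt,Insulin resistance,PD|MSA
latrepirdine,5,dmt,Bioenergetic mitochondrial agent,HD|AD
LMTM,1,dmt,Tau aggregation,FTLD|AD
metformin,1,dmt,Insulin resistance,FTLD|ALS
NBMI,1,dmt,Mercury chelation (oxidative stress),PSP|MSA
posiphen,1,dmt,Protein aggregation,PD|AD
TPI-287,1,dmt,Tau microtubule stabilizer,CBD|PSP
traneurocin,1,dmt,Neurogenesis,DLB|AD
warfarin,1,dmt,Vascular (anticoagulant),AD|HD
zoledronic acid,1,dmt,Bone loss prevention,PD|DLB|PSP|MSA
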