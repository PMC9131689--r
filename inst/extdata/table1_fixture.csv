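agent,n_trials,moa_class,goal,ndds
alprazolam,1,symptomatic,Reduced anxiety,HD|AD
ampreloxetine,1,symptomatic,Control of orthostatic hypotension,PD|MSA
apomorphine,1,symptomatic,Pain control,CBD|PSP
armodafinil,1,symptomatic,"Improved attention, cognitive enhancement",PD|DLB
AVP-786,1,symptomatic,Reduced disinhibition,DLB|AD|PSP|HD|FTLD
AVP-923,2,symptomatic,Control of pseudobulbar affect,AD|PD|HD|ALS
botulinum toxin,1,symptomatic,Reduction of rigidity,AD|FTLD
cannabis,2,symptomatic,"Improved sense of well-being, improved quality of life; reduction of pain, nausea, vomiting",PD|CTE|ALS
carbidopa,1,symptomatic,Improved motor function,MSA|PD
droxidopa,7,symptomatic,"Improved motor and non-motor symptoms, increased blood pressure",PD|MSA|PSP
entacapone,1,symptomatic,Improved motor function,MSA|PD
incobotulinum toxin a,2,symptomatic,Reduced salivary volume,PD|ALS|MSA|PSP
intepirdine,1,symptomatic,Improved gait,DLB|AD|PD
lithium,1,symptomatic,"Improved quality of life, reduced depression",CBD|PSP
LY3154207,1,symptomatic,Cognitive enhancement,DLB|PD
memantine,2,symptomatic,Cognitive enhancement,PD|DLB|FTLD|ALS
midodrine,4,symptomatic,Control of orthostatic hypotension,MSA|PD
MP-101,1,symptomatic,Reduction of dementia-related psychosis,AD|FTLD|PD|DLB
nebivolol,1,symptomatic,Control of hypotension,MSA|PD
nelotanserin,3,symptomatic,"Reduced REM sleep behavior disorders, reduced visual hallucinations",PD|DLB
NYX-458,1,symptomatic,Cognitive enhancement,PD|DLB
pimavanserin,2,symptomatic,Reduction of dementia-related psychosis with delusions and hallucinations,AD|PD|DLB|FTLD
ramalteon,1,symptomatic,Improved sleep efficiency,HD|DLB|PD
rimabotulinum toxin b,1,symptomatic,Reduced sialorrhea,PD|ALS
TD-9855,1,symptomatic,Reduced orthostatic hypotension,MSA|PD
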