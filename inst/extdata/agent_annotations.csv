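canonical_name,synonyms,moa_class,cadro,goal
alprazolam,,symptomatic,neurotransmitter receptors,Reduced anxiety
ampreloxetine,,symptomatic,neurotransmitter receptors,Control of orthostatic hypotension
apomorphine,,symptomatic,neurotransmitter receptors,Pain control
armodafinil,,symptomatic,neurotransmitter receptors,"Improved attention, cognitive enhancement"
AVP-786,deudextromethorphan,symptomatic,neurotransmitter receptors,Reduced disinhibition
AVP-923,dextromethorphan quinidine|nuedexta,symptomatic,neurotransmitter receptors,Control of pseudobulbar affect
botulinum toxin,,symptomatic,neurotransmitter receptors,Reduction of rigidity
cannabis,,symptomatic,neurotransmitter receptors,"Improved sense of well-being, improved quality of life; reduction of pain, nausea, vomiting"
carbidopa,,symptomatic,neurotransmitter receptors,Improved motor function
droxidopa,,symptomatic,neurotransmitter receptors,"Improved motor and non-motor symptoms, increased blood pressure"
entacapone,,symptomatic,neurotransmitter receptors,Improved motor function
incobotulinum toxin a,,symptomatic,neurotransmitter receptors,Reduced salivary volume
intepirdine,RVT-101,symptomatic,neurotransmitter receptors,Improved gait
lithium,,symptomatic,neurotransmitter receptors,"Improved quality of life, reduced depression"
LY3154207,,symptomatic,neurotransmitter receptors,Cognitive enhancement
memantine,,symptomatic,neurotransmitter receptors,Cognitive enhancement
midodrine,,symptomatic,neurotransmitter receptors,Control of orthostatic hypotension
MP-101,,symptomatic,neurotransmitter receptors,Reduction of dementia-related psychosis
nebivolol,,symptomatic,neurotransmitter receptors,Control of hypotension
nelotanserin,,symptomatic,neurotransmitter receptors,"Reduced REM sleep behavior disorders, reduced visual hallucinations"
NYX-458,,symptomatic,neurotransmitter receptors,Cognitive enhancement
pimavanserin,,symptomatic,neurotransmitter receptors,Reduction of dementia-related psychosis with delusions and hallucinations
ramalteon,ramelteon,symptomatic,neurotransmitter receptors,Improved sleep efficiency
rimabotulinum toxin b,,symptomatic,neurotransmitter receptors,Reduced sialorrhea
TD-9855,,symptomatic,neurotransmitter receptors,Reduced orthostatic hypotension
ATH-1017,fosgonimeton,dmt,synaptic plasticity/neuroprotection,Neuroprotection
BIIB092,gosuranemab,dmt,tau,Tau extracellular transmission
davunetide,AL-108|NAP,dmt,tau,Tau aggregation
deferiprone,,dmt,oxidative stress,Oxidative stress
insulin,intranasal insulin,dmt,metabolism and bioenergetics,Insulin resistance
latrepirdine,dimebon,dmt,metabolism and bioenergetics,Bioenergetic mitochondrial agent
LMTM,TRx0237|LMT-X,dmt,tau,Tau aggregation
metformin,,dmt,metabolism and bioenergetics,Insulin resistance
NBMI,"N,N'-bis(2-mercaptoethyl) isophthalamide|emeramide",dmt,oxidative stress,Mercury chelation (oxidative stress)
posiphen,,dmt,proteostasis/proteinopathies,Protein aggregation
TPI-287,abeotaxane,dmt,tau,Tau microtubule stabilizer
traneurocin,N-831,dmt,neurogenesis,Neurogenesis
warfarin,,dmt,vasculature,Vascular (anticoagulant)
zoledronic acid,,dmt,other,Bone loss prevention
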