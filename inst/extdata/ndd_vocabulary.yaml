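# Canonical neurodegenerative-disorder vocabulary.
# Each top-level label is a reporting label; variants include full names,
# abbreviations, alternate names and stage variants that fold into the label
# (PDD -> PD, LBD -> DLB, FTD -> FTLD). Matching is case/punctuation
# insensitive; abbreviations (short tokens) match only as standalone words;
# strings of >= 8 characters additionally match within `fuzzy_threshold`
# edits. The bare word "dementia" is deliberately absent: unqualified
# dementia populations are not attributable to a single disorder.
fuzzy_threshold: 1
labels:
  AD:
    - Alzheimer Disease
    - Alzheimer's Disease
    - Alzheimers Disease
    - Alzheimer Dementia
    - Alzheimer's Dementia
    - Dementia of the Alzheimer Type
    - Alzheimer Type Dementia
    - AD
  PD:
    - Parkinson Disease
    - Parkinson's Disease
    - Parkinsons Disease
    - Idiopathic Parkinson Disease
    - Idiopathic Parkinson's Disease
    - PD
    # stage variants folded into PD
    - Parkinson Disease Dementia
    - Parkinson's Disease Dementia
    - Parkinsons Disease Dementia
    - PDD
  DLB:
    - Dementia With Lewy Bodies
    - Lewy Body Dementia
    - Lewy Body Disease
    - Diffuse Lewy Body Disease
    - DLB
    # alternate umbrella label folded into DLB
    - LBD
  FTLD:
    - Frontotemporal Lobar Degeneration
    - Frontotemporal Degeneration
    - FTLD
    # FTD folds into FTLD
    - Frontotemporal Dementia
    - Fronto-Temporal Dementia
    - Behavioral Variant Frontotemporal Dementia
    - FTD
  PSP:
    - Progressive Supranuclear Palsy
    - Supranuclear Palsy Progressive
    - PSP
  CBD:
    - Corticobasal Degeneration
    - Cortico-Basal Degeneration
    - Corticobasal Syndrome
    - Corticobasal Ganglionic Degeneration
    - CBD
  CTE:
    - Chronic Traumatic Encephalopathy
    - Traumatic Encephalopathy Syndrome
    - CTE
  HD:
    - Huntington Disease
    - Huntington's Disease
    - Huntingtons Disease
    - Huntington Chorea
    - Huntington's Chorea
    - HD
  ALS:
    - Amyotrophic Lateral Sclerosis
    - Lou Gehrig Disease
    - Lou Gehrig's Disease
    - ALS
  MSA:
    - Multiple System Atrophy
    - Multiple Systems Atrophy
    - Shy-Drager Syndrome
    - Multiple System Atrophy Parkinsonian Type
    - Multiple System Atrophy Cerebellar Type
    - MSA
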