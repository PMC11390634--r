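# 29 FinnGen-style pain endpoint labels scanned against each gated drug
# class. Names are opaque labels; users may supply their own panel.
- migraine
- migraine_without_aura
- migraine_with_aura
- tension_headache
- headache
- trigeminal_neuralgia
- neuralgia_neuritis_nas
- radiculopathy
- sciatica
- dorsalgia
- dorsalgianas
- low_back_pain
- neck_pain
- limb_pain
- joint_pain
- myalgia
- fibromyalgia
- coxarthrosis
- gonarthrosis
- panniculitis
- chest_pain
- abdominal_pain
- pelvic_pain
- femgenpain
- dysmenorrhea
- earache
- dental_pain
- chronic_pain_nas
- pain_unspecified
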