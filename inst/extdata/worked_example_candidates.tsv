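# Worked-example per-component translation-candidate columns for the
# 2-to-2 case 心房 颤动 -> "atrial fibrillation" and the 2-to-1 case
# 吞咽 困难 -> "dysphagia" (synthetic reconstruction of the kind of noisy
# candidate lists label propagation produces for real clinical corpora).
# Both correct-translation words appear in both of their components'
# columns, which is the property the aligner exploits.
component	rank	candidate
心房	1	bradycardia
心房	2	fibrillation
心房	3	syncope
心房	4	angina
心房	5	fever
心房	6	acidosis
心房	7	pericarditis
心房	8	cesarean
心房	9	heart
心房	10	leukemia
心房	11	glaucoma
心房	12	cardiomyopathy
心房	13	atrial
心房	14	encephalopathy
心房	15	hypothyroidism
心房	16	bronchitis
心房	17	bacteremia
心房	18	thrombocytopenia
颤动	1	bradycardia
颤动	2	fibrillation
颤动	3	acidosis
颤动	4	angina
颤动	5	depression
颤动	6	rheumatoid
颤动	7	myocardial
颤动	8	bloody
颤动	9	jaundice
颤动	10	heart
颤动	11	sepsis
颤动	12	bloody
颤动	13	glaucoma
颤动	14	dysphagia
颤动	15	atrial
颤动	16	respiratory
颤动	17	leukemia
颤动	18	bacteremia
吞咽	1	hematuria
吞咽	2	dysphagia
吞咽	3	acidosis
吞咽	4	stools
吞咽	5	fever
吞咽	6	acidosis
吞咽	7	jaundice
吞咽	8	anemia
吞咽	9	encephalopathy
吞咽	10	heart
吞咽	11	anemia
吞咽	12	rheumatoid
吞咽	13	sepsis
吞咽	14	respiratory
吞咽	15	cardiomyopathy
吞咽	16	encephalopathy
吞咽	17	cesarean
吞咽	18	palsy
困难	1	hematuria
困难	2	syncope
困难	3	dysphagia
困难	4	syncope
困难	5	stools
困难	6	fever
困难	7	hypothyroidism
困难	8	acidosis
困难	9	pericarditis
困难	10	anemia
困难	11	jaundice
困难	12	leukemia
困难	13	angina
困难	14	sepsis
困难	15	thrombocytopenia
困难	16	encephalopathy
困难	17	hypothyroidism
困难	18	anemia
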