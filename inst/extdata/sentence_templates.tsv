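# Sentence template bank for the synthetic note generator.
# Columns: kind <TAB> axis <TAB> text
# axis "*" means any axis. Placeholders: {PAT} compact TNM pattern (with or
# without c/p prefix), {TERM} a narrative target-term surface, {NUM} a lab
# value, {SMALLNUM} a small integer, {OVER} an overall stage group 1-4.
compact_frame	*	Staging: {PAT}.
compact_frame	*	Final staging {PAT}.
compact_frame	*	TNM assessment: {PAT}.
compact_frame	*	Assigned stage {PAT}.
compact_frame	*	Staging at this visit: {PAT}.
compact_frame	*	AJCC designation {PAT}.
narrative_frame	*	{TERM} was identified.
narrative_frame	*	Findings demonstrate {TERM}.
narrative_frame	*	There is {TERM}.
narrative_frame	*	Exam notable for {TERM}.
narrative_frame	*	Impression: {TERM}.
narrative_frame	*	Biopsy shows {TERM}.
ambiguous_frame	*	he has {PAT} prostate cancer.
ambiguous_frame	*	patient with {PAT} disease.
ambiguous_frame	*	known {PAT} prostate cancer.
ambiguous_frame	*	consistent with {PAT} prostate ca.
ambiguous_frame	*	documented {PAT} disease.
n0_phrase	N	No evidence of nodal metastasis.
n0_phrase	N	There is no evidence of regional lymph node metastasis.
n0_phrase	N	No lymph node involvement was identified.
n0_phrase	N	Imaging shows no pelvic lymphadenopathy.
n0_phrase	N	Without evidence of nodal involvement.
n0_phrase	N	No regional lymph node metastasis identified.
m0_phrase	M	No evidence of distant metastasis.
m0_phrase	M	Bone scan shows no bone metastases.
m0_phrase	M	There is no evidence of metastatic disease.
m0_phrase	M	Without distant metastases.
m0_phrase	M	Staging workup negative for distant metastasis.
historical_frame	*	history of {TERM}.
historical_frame	*	previously noted {TERM}.
historical_frame	*	past medical history of {TERM}.
historical_frame	*	status post treatment for {TERM}.
historical_frame	*	known prior {TERM}.
hypothetical_frame	*	will discuss if {TERM} develops.
hypothetical_frame	*	return if {TERM} occurs.
hypothetical_frame	*	there is concern for possible {TERM}.
hypothetical_frame	*	risk of {TERM} was discussed.
hypothetical_frame	*	monitor for {TERM}.
distractor	*	PSA {NUM} ng/ml, stable.
distractor	*	Continue tamsulosin 0.4 mg daily.
distractor	*	Patient reports good urinary function.
distractor	*	Vital signs stable, afebrile.
distractor	*	Discussed treatment options at length.
distractor	*	Review of systems otherwise unremarkable.
distractor	*	Follow up in {SMALLNUM} months.
distractor	*	Creatinine {NUM}, within normal limits.
distractor	*	He denies dysuria or hematuria.
distractor	*	Seen by Dr. Smith in clinic today.
overall_stage	*	stage {OVER} prostate cancer was discussed.
overall_stage	*	consistent with stage {OVER} prostate cancer.
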