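# Target staging terms for prostate cancer TNM extraction.
# Columns: surface <TAB> axis <TAB> numeral <TAB> kind <TAB> source
# axis in {T,N,M}; numeral empty for anchor terms that carry no stage value;
# kind in {clinical,pathological,unspecified}; source in {AJCC,expert,embedding_expansion}.
# Phrasings follow AJCC 7th-edition prostate criteria plus common narrative synonyms.
clinically inapparent tumor	T	1	clinical	AJCC
nonpalpable tumor	T	1	clinical	expert
non-palpable tumor	T	1	clinical	expert
tumor identified by needle biopsy	T	1	clinical	AJCC
incidental histologic finding	T	1	clinical	AJCC
incidental finding at transurethral resection	T	1	clinical	expert
organ confined	T	2	pathological	expert
organ-confined disease	T	2	pathological	expert
tumor confined within the prostate	T	2	unspecified	AJCC
confined to the prostate	T	2	unspecified	expert
disease confined to the gland	T	2	unspecified	expert
palpable nodule confined to the prostate	T	2	clinical	expert
involves one half of one lobe or less	T	2	clinical	AJCC
involves more than one half of one lobe	T	2	clinical	AJCC
involves both lobes	T	2	clinical	AJCC
tumor palpable in one lobe	T	2	clinical	expert
palpable bilateral nodules	T	2	clinical	expert
extracapsular extension	T	3	unspecified	AJCC
extraprostatic extension	T	3	unspecified	AJCC
focal extraprostatic extension	T	3	pathological	expert
established extraprostatic extension	T	3	pathological	expert
extends through the prostatic capsule	T	3	unspecified	AJCC
extension beyond the capsule	T	3	unspecified	expert
tumor extends beyond the prostate	T	3	unspecified	expert
capsular penetration	T	3	pathological	expert
seminal vesicle invasion	T	3	unspecified	AJCC
seminal vesicle involvement	T	3	unspecified	expert
invades the seminal vesicles	T	3	unspecified	AJCC
ece	T	3	pathological	expert
epe	T	3	pathological	expert
svi	T	3	pathological	expert
locally advanced disease	T	3	clinical	embedding_expansion
invades the bladder	T	4	unspecified	AJCC
invades the rectum	T	4	unspecified	AJCC
invades the external sphincter	T	4	unspecified	AJCC
invades the levator muscles	T	4	unspecified	AJCC
involvement of the external sphincter	T	4	unspecified	expert
fixed to the pelvic wall	T	4	unspecified	AJCC
fixed tumor	T	4	clinical	expert
carcinoma fixed to adjacent structures	T	4	unspecified	expert
regional lymph node metastasis	N	1	unspecified	AJCC
regional lymph node metastases	N	1	unspecified	AJCC
lymph node metastasis	N	1	unspecified	expert
lymph node metastases	N	1	unspecified	expert
lymph node involvement	N	1	unspecified	expert
nodal metastasis	N	1	unspecified	expert
nodal metastases	N	1	unspecified	expert
nodal involvement	N	1	unspecified	expert
pelvic lymphadenopathy	N	1	unspecified	expert
pelvic lymph node metastasis	N	1	unspecified	expert
positive lymph nodes	N	1	pathological	expert
positive pelvic nodes	N	1	pathological	expert
tumor in lymph nodes	N	1	pathological	expert
metastatic carcinoma in lymph nodes	N	1	pathological	expert
micrometastasis in lymph node	N	1	pathological	expert
node positive disease	N	1	unspecified	embedding_expansion
distant metastasis	M	1	unspecified	AJCC
distant metastases	M	1	unspecified	AJCC
metastatic disease	M	1	unspecified	expert
bone metastasis	M	1	unspecified	expert
bone metastases	M	1	unspecified	expert
osseous metastatic disease	M	1	unspecified	expert
metastatic prostate cancer	M	1	clinical	expert
widely metastatic disease	M	1	clinical	embedding_expansion
nonregional lymph node metastasis	M	1	unspecified	AJCC
visceral metastasis	M	1	unspecified	AJCC
skeletal metastases	M	1	unspecified	expert
metastatic disease to bone	M	1	unspecified	expert
distant organ involvement	M	1	unspecified	expert
primary tumor	T		unspecified	AJCC
tumor size	T		unspecified	expert
digital rectal examination	T		clinical	expert
digital rectal exam	T		clinical	expert
dre	T		clinical	expert
prostate biopsy	T		unspecified	expert
prostate needle biopsy	T		unspecified	expert
prostatectomy specimen	T		pathological	expert
radical prostatectomy	T		pathological	expert
transurethral resection	T		unspecified	expert
prostatic capsule	T		unspecified	AJCC
apex of the prostate	T		pathological	expert
clinical stage	T		clinical	expert
pathological stage	T		pathological	expert
pathologic stage	T		pathological	expert
tumor stage	T		unspecified	expert
t stage	T		unspecified	expert
staging	T		unspecified	expert
tnm stage	T		unspecified	expert
gleason score	T		unspecified	expert
gleason	T		unspecified	expert
adenocarcinoma of the prostate	T		unspecified	expert
prostate nodule	T		clinical	expert
surgical margins	T		pathological	expert
prostate gland	T		unspecified	expert
lymph node	N		unspecified	AJCC
lymph nodes	N		unspecified	AJCC
pelvic lymph node dissection	N		pathological	expert
lymphadenectomy	N		pathological	expert
regional nodes	N		unspecified	AJCC
n stage	N		unspecified	expert
nodal status	N		unspecified	expert
lymphadenopathy	N		unspecified	expert
obturator nodes	N		unspecified	expert
iliac nodes	N		unspecified	expert
bone scan	M		clinical	expert
whole body bone scan	M		clinical	expert
metastasis	M		unspecified	AJCC
metastases	M		unspecified	AJCC
metastatic	M		unspecified	expert
m stage	M		unspecified	expert
skeletal survey	M		clinical	expert
pet scan	M		clinical	expert
distant spread	M		unspecified	embedding_expansion
osseous lesions	M		unspecified	embedding_expansion
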