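asthme	mesh_term
asthme du nourrisson	mesh_term
hépatite	mesh_term
hépatite a	mesh_term
hépatite b	mesh_term
hépatite c	mesh_term
hépatite virale	mesh_synonym
cholestérol	mesh_term
hypercholestérolémie	mesh_term
alzheimer	cismef_synonym
maladie d'alzheimer	mesh_term
acupuncture	mesh_term
rickettsioses	mesh_term
suette miliaire	mesh_term
creutzfeldt-jakob	cismef_synonym
maladie de creutzfeldt-jakob	mesh_term
trigonocéphalie	mesh_term
hyperaldostéronisme	mesh_term
amygdale	mesh_term
amygdalite	mesh_term
tumeurs du sein	mesh_term
cancer du sein	mesh_synonym
thérapeutique	mesh_term
insomnie	mesh_term
insomnia	mesh_synonym
inosine	mesh_term
euthanasia	mesh_synonym
euthanasie	mesh_term
sang	mesh_term
tabac	mesh_term
tabagisme	mesh_term
circulation accident	mesh_synonym
accidents de la circulation	mesh_term
chute accidentelle	mesh_synonym
chutes accidentelles	mesh_term
sida	mesh_term
lymphome lié sida	mesh_synonym
sida atteinte neurologique	mesh_synonym
glucosidases	mesh_term
bêta galactosidase	mesh_synonym
grippe	mesh_term
grippe humaine	mesh_synonym
vaccins antigrippaux	mesh_term
diabète	mesh_term
diabète de type 2	mesh_term
diabète gestationnel	mesh_term
hypertension artérielle	mesh_term
hypotension	mesh_term
cancer	cismef_synonym
tumeurs	mesh_term
tumeurs du poumon	mesh_term
cancer du poumon	mesh_synonym
tumeurs de la prostate	mesh_term
tumeurs de l'estomac	mesh_term
tumeurs du colon	mesh_term
leucémie	mesh_term
lymphome	mesh_term
mélanome	mesh_term
anémie	mesh_term
anémie ferriprive	mesh_term
hémophilie	mesh_term
hémorragie	mesh_term
thrombose veineuse	mesh_term
embolie pulmonaire	mesh_term
infarctus du myocarde	mesh_term
insuffisance cardiaque	mesh_term
arythmie cardiaque	mesh_term
tachycardie	mesh_term
bradycardie	mesh_term
athérosclérose	mesh_term
angine de poitrine	mesh_term
accident vasculaire cérébral	mesh_term
épilepsie	mesh_term
migraine	mesh_term
céphalée	mesh_term
sclérose en plaques	mesh_term
maladie de parkinson	mesh_term
méningite	mesh_term
encéphalite	mesh_term
neuropathie périphérique	mesh_term
dépression	mesh_term
anxiété	mesh_term
schizophrénie	mesh_term
troubles bipolaires	mesh_term
anorexie mentale	mesh_term
boulimie	mesh_term
autisme	mesh_term
bronchite	mesh_term
bronchiolite	mesh_term
pneumonie	mesh_term
pneumopathie	mesh_synonym
tuberculose	mesh_term
mucoviscidose	mesh_term
emphysème pulmonaire	mesh_term
apnée du sommeil	mesh_term
sinusite	mesh_term
rhinite allergique	mesh_term
otite	mesh_term
otite moyenne	mesh_term
laryngite	mesh_term
pharyngite	mesh_term
gastrite	mesh_term
ulcère gastrique	mesh_term
reflux gastro-oesophagien	mesh_term
appendicite	mesh_term
pancréatite	mesh_term
cirrhose du foie	mesh_term
foie	mesh_term
calculs biliaires	mesh_term
colite ulcéreuse	mesh_term
maladie de crohn	mesh_term
constipation	mesh_term
diarrhée	mesh_term
gastro-entérite	mesh_term
insuffisance rénale	mesh_term
calculs rénaux	mesh_term
cystite	mesh_term
infections urinaires	mesh_term
incontinence urinaire	mesh_term
prostatite	mesh_term
endométriose	mesh_term
fibrome utérin	mesh_term
grossesse	mesh_term
grossesse extra-utérine	mesh_term
accouchement	mesh_term
avortement spontané	mesh_term
ménopause	mesh_term
contraception	mesh_term
infertilité	mesh_term
eczéma	mesh_term
psoriasis	mesh_term
acné	mesh_term
urticaire	mesh_term
dermatite atopique	mesh_term
zona	mesh_term
varicelle	mesh_term
rougeole	mesh_term
rubéole	mesh_term
oreillons	mesh_term
coqueluche	mesh_term
scarlatine	mesh_term
paludisme	mesh_term
toxoplasmose	mesh_term
listériose	mesh_term
salmonellose	mesh_term
méningocoque	mesh_synonym
staphylocoque	mesh_synonym
streptocoque	mesh_synonym
herpès	mesh_term
papillomavirus	mesh_term
vaccination	mesh_term
vaccins	mesh_term
allergie	mesh_term
allergie alimentaire	mesh_term
arthrose	mesh_term
arthrite	mesh_term
polyarthrite rhumatoïde	mesh_term
ostéoporose	mesh_term
scoliose	mesh_term
lombalgie	mesh_term
sciatique	mesh_synonym
fracture	mesh_term
entorse	mesh_synonym
tendinite	mesh_synonym
fibromyalgie	mesh_term
goutte	mesh_term
lupus érythémateux	mesh_term
hypothyroïdie	mesh_term
hyperthyroïdie	mesh_term
goitre	mesh_term
obésité	mesh_term
malnutrition	mesh_term
carence en fer	mesh_synonym
vitamine d	mesh_term
cataracte	mesh_term
glaucome	mesh_term
conjonctivite	mesh_term
myopie	mesh_term
strabisme	mesh_term
surdité	mesh_term
acouphène	mesh_term
vertige	mesh_term
caries dentaires	mesh_term
gingivite	mesh_term
parodontite	mesh_term
stomatite	mesh_term
oreille	mesh_term
estomac	mesh_term
poumon	mesh_term
genou	mesh_term
épaule	mesh_term
cheville	mesh_term
colonne vertébrale	mesh_term
moelle osseuse	mesh_term
thérapie génique	mesh_term
chimiothérapie	mesh_term
radiothérapie	mesh_term
physiothérapie	mesh_term
kinésithérapie	cismef_synonym
psychothérapie	mesh_term
antibiotiques	mesh_term
anticoagulants	mesh_term
antidépresseurs	mesh_term
anti-inflammatoires	mesh_term
paracétamol	mesh_term
ibuprofène	mesh_term
aspirine	mesh_term
insuline	mesh_term
corticoïdes	mesh_synonym
soins palliatifs	mesh_term
médecine générale	mesh_term
chirurgie	mesh_term
anesthésie	mesh_term
greffe de rein	mesh_synonym
transplantation rénale	mesh_term
dialyse rénale	mesh_term
échographie	mesh_term
radiographie	mesh_term
scanner	cismef_synonym
imagerie par résonance magnétique	mesh_term
électrocardiographie	mesh_term
biopsie	mesh_term
dépistage	mesh_term
prévention	mesh_synonym
nutrition	mesh_term
régime alimentaire	mesh_term
exercice physique	mesh_term
sommeil	mesh_term
stress psychologique	mesh_term
douleur	mesh_term
douleur chronique	mesh_term
fièvre	mesh_term
fatigue	mesh_term
toux	mesh_term
science	mesh_term
angine	mesh_term
androstènes	mesh_term
androstenols	mesh_term
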