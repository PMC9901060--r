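category	medication
ACEI	Benazepril
ACEI	Lotensin
ACEI	Captopril
ACEI	Enalapril
ACEI	Vasotec
ACEI	Fosinopril
ACEI	Lisinopril
ACEI	Prinivil
ACEI	Zestril
ACEI	Moexipril
ACEI	Perindopril
ACEI	Quinapril
ACEI	Accupril
ACEI	Ramipril
ACEI	Altace
ACEI	Trandolapril
BB	Acebutolol
BB	Atenolol
BB	Tenormin
BB	Bisoprolol
BB	Zebeta
BB	Metoprolol
BB	Lopressor
BB	Toprol XL
BB	Nadolol
BB	Corgard
BB	Nebivolol
BB	Bystolic
BB	Propranolol
BB	Inderal
BB	InnoPran XL
ARB	Azilsartan
ARB	Edarbi
ARB	Candesartan
ARB	Atacand
ARB	Eprosartan
ARB	Irbesartan
ARB	Avapro
ARB	Losartan
ARB	Cozaar
ARB	Olmesartan
ARB	Benicar
ARB	Telmisartan
ARB	Micardis
ARB	Valsartan
ARB	Diovan
Statin	Atorvastatin
Statin	Lipitor
Statin	Lovastatin
Statin	Altoprev
Statin	Pitavastatin
Statin	Livalo
Statin	Zypitamag
Statin	Pravastatin
Statin	Pravachol
Statin	Rosuvastatin
Statin	Crestor
Statin	Ezallor
Statin	Simvastatin
Statin	Zocor
LD	Chlorothiazide
LD	Chlorthalidone
LD	Hydrochlorothiazide
LD	Indapamide
LD	Metolazone
LD	Bumetanide
LD	Bumex
LD	Ethacrynic acid
LD	Edecrin
LD	Furosemide
LD	Lasix
LD	Torsemide
LD	Soaanz
LD	Amiloride
LD	Midamor
LD	Eplerenone
LD	Inspra
LD	Spironolactone
LD	Aldactone
LD	Carospir
LD	Triamterene
LD	Dyrenium
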