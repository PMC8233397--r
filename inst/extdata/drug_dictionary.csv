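ingredient,class,alias
captopril,ACEI,captopril
captopril,ACEI,capoten
lisinopril,ACEI,lisinopril
lisinopril,ACEI,prinivil
lisinopril,ACEI,zestril
quinapril,ACEI,quinapril
quinapril,ACEI,accupril
quinapril,ACEI,accupro
ramipril,ACEI,ramipril
ramipril,ACEI,altace
ramipril,ACEI,tritace
enalapril,ACEI,enalapril
enalapril,ACEI,vasotec
enalapril,ACEI,renitec
perindopril,ACEI,perindopril
perindopril,ACEI,aceon
perindopril,ACEI,coversyl
fosinopril,ACEI,fosinopril
fosinopril,ACEI,monopril
cilazapril,ACEI,cilazapril
cilazapril,ACEI,inhibace
benazepril,ACEI,benazepril
benazepril,ACEI,lotensin
trandolapril,ACEI,trandolapril
trandolapril,ACEI,mavik
azilsartan,ARB,azilsartan
azilsartan,ARB,edarbi
irbesartan,ARB,irbesartan
irbesartan,ARB,avapro
irbesartan,ARB,aprovel
losartan,ARB,losartan
losartan,ARB,cozaar
olmesartan,ARB,olmesartan
olmesartan,ARB,benicar
olmesartan,ARB,olmetec
telmisartan,ARB,telmisartan
telmisartan,ARB,micardis
valsartan,ARB,valsartan
valsartan,ARB,diovan
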