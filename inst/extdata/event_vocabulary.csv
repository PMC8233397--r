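preferred_term,synonym
pulmonary edema,pulmonary edema
pulmonary edema,pulmonary oedema
pulmonary edema,lung edema
pleural effusion,pleural effusion
pleural effusion,fluid on the lungs
oropharyngeal pain,oropharyngeal pain
oropharyngeal pain,sore throat
oropharyngeal pain,throat pain
dyspnea,dyspnea
dyspnea,dyspnoea
dyspnea,shortness of breath
dyspnea,breathlessness
dysphonia,dysphonia
dysphonia,hoarseness
cough,cough
cough,coughing
cough,dry cough
sinusitis,sinusitis
sinusitis,sinus infection
pneumonia,pneumonia
pneumonia,lung infection
nasopharyngitis,nasopharyngitis
nasopharyngitis,common cold
bronchitis,bronchitis
pneumonia aspiration,pneumonia aspiration
pneumonia aspiration,aspiration pneumonia
emphysema,emphysema
pleurisy,pleurisy
pleurisy,pleuritic pain
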