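smq	pt	scope
Malignant tumours of the skin	Basal cell carcinoma	narrow
Malignant tumours of the skin	Squamous cell carcinoma of skin	narrow
Malignant tumours of the skin	Lentigo maligna	narrow
Malignant tumours of the skin	Neuroendocrine carcinoma of the skin	narrow
Cutaneous premalignant conditions	Bowen's disease	narrow
Cutaneous premalignant conditions	Keratoacanthoma	broad
Severe cutaneous adverse reactions	Stevens-Johnson syndrome	narrow
Severe cutaneous adverse reactions	Dermatitis exfoliative generalised	narrow
Severe cutaneous adverse reactions	Drug reaction with eosinophilia and systemic symptoms	narrow
Severe cutaneous adverse reactions	Acute generalised exanthematous pustulosis	narrow
Severe cutaneous adverse reactions	Erythema multiforme	broad
Severe cutaneous adverse reactions	Toxic skin eruption	broad
Severe cutaneous adverse reactions	Cutaneous vasculitis	broad
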