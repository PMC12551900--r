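variant	ingredient
ENZALUTAMIDE	enzalutamide
XTANDI	enzalutamide
MDV3100	enzalutamide
APALUTAMIDE	apalutamide
ERLEADA	apalutamide
ARN-509	apalutamide
DAROLUTAMIDE	darolutamide
NUBEQA	darolutamide
ODM-201	darolutamide
ABIRATERONE	abiraterone
ABIRATERONE ACETATE	abiraterone
ZYTIGA	abiraterone
YONSA	abiraterone
LEUPROLIDE	leuprolide
LEUPROLIDE ACETATE	leuprolide
LUPRON	leuprolide
ELIGARD	leuprolide
GOSERELIN	goserelin
ZOLADEX	goserelin
DEGARELIX	degarelix
FIRMAGON	degarelix
PREDNISONE	prednisone
DOCETAXEL	docetaxel
TAXOTERE	docetaxel
METFORMIN	metformin
ATORVASTATIN	atorvastatin
LIPITOR	atorvastatin
LISINOPRIL	lisinopril
OMEPRAZOLE	omeprazole
PRILOSEC	omeprazole
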