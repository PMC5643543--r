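site	comparison	disease	healthy
gut	HIV-ART/Negative	HIV-ART	HIV-Negative
gut	HIV-NonART/Negative	HIV-NonART	HIV-Negative
gut	IBD-CD/IBD-Healthy	IBD-CD	IBD-Healthy
gut	IBD-UC/IBD-Healthy	IBD-UC	IBD-Healthy
lung	Exacerbation/Treatment	Lung-Exacerbation	Lung-EndOfTreatment
oral	PB/Healthy	Oral-PB	Oral-Healthy
oral	PnB/Healthy	Oral-PnB	Oral-Healthy
skin	AD/Healthy	Skin-AD	Skin-Healthy
vaginal	BV/Healthy	Vaginal-BV	Vaginal-Healthy
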