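sample_id,sample_type,locus,alleles
V1,grapevine,VVMD21,235/241
V1,grapevine,VVMD25,273/277
V1,grapevine,VVMD27,203/215
V1,grapevine,VVMD32,231/231
V1,grapevine,VVMD34,265/265
V1,grapevine,VVS2,165/167
V1,grapevine,VrZag21,207/209
V1,grapevine,VrZag79,241/241
V1,grapevine,VrZag83,189/193
V2,grapevine,VVMD21,239/243
V2,grapevine,VVMD25,273/275
V2,grapevine,VVMD27,215/217
V2,grapevine,VVMD32,239/241
V2,grapevine,VVMD34,277/277
V2,grapevine,VVS2,159/169
V2,grapevine,VrZag21,213/213
V2,grapevine,VrZag79,233/247
V2,grapevine,VrZag83,187/199
V3,grapevine,VVMD21,237/239
V3,grapevine,VVMD25,275/279
V3,grapevine,VVMD27,215/217
V3,grapevine,VVMD32,235/235
V3,grapevine,VVMD34,265/275
V3,grapevine,VVS2,161/169
V3,grapevine,VrZag21,211/215
V3,grapevine,VrZag79,233/241
V3,grapevine,VrZag83,189/199
V4,grapevine,VVMD21,231/237
V4,grapevine,VVMD25,273/277
V4,grapevine,VVMD27,215/217
V4,grapevine,VVMD32,235/237
V4,grapevine,VVMD34,267/269
V4,grapevine,VVS2,159/167
V4,grapevine,VrZag21,205/207
V4,grapevine,VrZag79,237/243
V4,grapevine,VrZag83,193/199
MonoWine,wine,VVMD21,235/241
MonoWine,wine,VVMD25,273/277
MonoWine,wine,VVMD27,203/215
MonoWine,wine,VVMD32,231
MonoWine,wine,VVMD34,265
MonoWine,wine,VVS2,165/167
MonoWine,wine,VrZag21,207/209
MonoWine,wine,VrZag79,241
MonoWine,wine,VrZag83,189/193
BlendWine,wine,VVMD21,237/239/243
BlendWine,wine,VVMD25,273/275
BlendWine,wine,VVMD27,215/217
BlendWine,wine,VVMD32,239/241
BlendWine,wine,VVMD34,265/275/277
BlendWine,wine,VVS2,159/161/169
BlendWine,wine,VrZag21,211/213/215
BlendWine,wine,VrZag79,233/241/247
BlendWine,wine,VrZag83,187/189/199
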