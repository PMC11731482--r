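condition	prefix
hypertension	401
hypertension	402
hypertension	403
hypertension	405
hypertension	I10
hypertension	I11
hypertension	I12
hypertension	I13
hypertension	I14
hypertension	I15
hypertension	I16
atherosclerosis	414
atherosclerosis	437
atherosclerosis	I25
cerebrovascular	437
cerebrovascular	I673
cerebrovascular	I69
diabetes	249
diabetes	250
diabetes	E09
diabetes	E10
diabetes	E11
diabetes	E13
ihd_mi	2129
ihd_mi	410
ihd_mi	411
ihd_mi	412
ihd_mi	413
ihd_mi	414
ihd_mi	4292
ihd_mi	I20
ihd_mi	I21
ihd_mi	I22
ihd_mi	I23
ihd_mi	I24
ihd_mi	I25
ihd_mi	I312
ihd_mi	I513
ihd_mi	I51
ihd_mi	I829
ihd_mi	I97
ihd_mi	I998
ihd_mi	Q21
ihd_mi	Q899
ihd_mi	Z136
malignancy	140
malignancy	141
malignancy	142
malignancy	143
malignancy	144
malignancy	145
malignancy	146
malignancy	147
malignancy	148
malignancy	149
malignancy	150
malignancy	151
malignancy	152
malignancy	153
malignancy	154
malignancy	155
malignancy	156
malignancy	157
malignancy	158
malignancy	159
malignancy	160
malignancy	161
malignancy	162
malignancy	163
malignancy	164
malignancy	165
malignancy	166
malignancy	167
malignancy	168
malignancy	169
malignancy	170
malignancy	171
malignancy	172
malignancy	173
malignancy	174
malignancy	175
malignancy	176
malignancy	177
malignancy	178
malignancy	179
malignancy	180
malignancy	181
malignancy	182
malignancy	183
malignancy	184
malignancy	185
malignancy	186
malignancy	187
malignancy	188
malignancy	189
malignancy	190
malignancy	191
malignancy	192
malignancy	193
malignancy	194
malignancy	195
malignancy	196
malignancy	197
malignancy	198
malignancy	199
malignancy	200
malignancy	201
malignancy	202
malignancy	203
malignancy	204
malignancy	205
malignancy	206
malignancy	207
malignancy	208
malignancy	209
malignancy	210
malignancy	211
malignancy	212
malignancy	213
malignancy	214
malignancy	215
malignancy	216
malignancy	217
malignancy	218
malignancy	219
malignancy	220
malignancy	221
malignancy	222
malignancy	223
malignancy	224
malignancy	225
malignancy	226
malignancy	227
malignancy	228
malignancy	229
malignancy	230
malignancy	231
malignancy	232
malignancy	233
malignancy	234
malignancy	235
malignancy	236
malignancy	237
malignancy	238
malignancy	239
malignancy	C00
malignancy	C01
malignancy	C02
malignancy	C03
malignancy	C04
malignancy	C05
malignancy	C06
malignancy	C07
malignancy	C08
malignancy	C09
malignancy	C10
malignancy	C11
malignancy	C12
malignancy	C13
malignancy	C14
malignancy	C15
malignancy	C16
malignancy	C17
malignancy	C18
malignancy	C19
malignancy	C20
malignancy	C21
malignancy	C22
malignancy	C23
malignancy	C24
malignancy	C25
malignancy	C26
malignancy	C27
malignancy	C28
malignancy	C29
malignancy	C30
malignancy	C31
malignancy	C32
malignancy	C33
malignancy	C34
malignancy	C35
malignancy	C36
malignancy	C37
malignancy	C38
malignancy	C39
malignancy	C40
malignancy	C41
malignancy	C42
malignancy	C43
malignancy	C44
malignancy	C45
malignancy	C46
malignancy	C47
malignancy	C48
malignancy	C49
malignancy	C50
malignancy	C51
malignancy	C52
malignancy	C53
malignancy	C54
malignancy	C55
malignancy	C56
malignancy	C57
malignancy	C58
malignancy	C59
malignancy	C60
malignancy	C61
malignancy	C62
malignancy	C63
malignancy	C64
malignancy	C65
malignancy	C66
malignancy	C67
malignancy	C68
malignancy	C69
malignancy	C70
malignancy	C71
malignancy	C72
malignancy	C73
malignancy	C74
malignancy	C75
malignancy	C76
malignancy	C77
malignancy	C78
malignancy	C79
malignancy	C80
malignancy	C81
malignancy	C82
malignancy	C83
malignancy	C84
malignancy	C85
malignancy	C86
malignancy	C87
malignancy	C88
malignancy	C89
malignancy	C90
malignancy	C91
malignancy	C92
malignancy	C93
malignancy	C94
malignancy	C95
malignancy	C96
malignancy	D00
malignancy	D01
malignancy	D02
malignancy	D03
malignancy	D04
malignancy	D05
malignancy	D06
malignancy	D07
malignancy	D08
malignancy	D09
malignancy	D10
malignancy	D11
malignancy	D12
malignancy	D13
malignancy	D14
malignancy	D15
malignancy	D16
malignancy	D17
malignancy	D18
malignancy	D19
malignancy	D20
malignancy	D21
malignancy	D22
malignancy	D23
malignancy	D24
malignancy	D25
malignancy	D26
malignancy	D27
malignancy	D28
malignancy	D29
malignancy	D30
malignancy	D31
malignancy	D32
malignancy	D33
malignancy	D34
malignancy	D35
malignancy	D36
malignancy	D37
malignancy	D38
malignancy	D39
malignancy	D40
malignancy	D41
malignancy	D42
malignancy	D43
malignancy	D44
malignancy	D45
malignancy	D46
malignancy	D47
malignancy	D48
malignancy	D49
malignancy	H47
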