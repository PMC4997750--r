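subject_id	group	stage_label	screen_result	aneuploidy_call
S01	case	early	positive	no_call
S02	case	early	positive	no_call
S03	case	early	positive	low_risk
S04	case	early	positive	low_risk
S05	case	early	positive	low_risk
S06	case	early	positive	low_risk
S07	case	advanced	positive	no_call
S08	case	advanced	positive	low_risk
S09	case	advanced	positive	low_risk
S10	case	advanced	positive	low_risk
S11	case	advanced	positive	no_call
S12	case	advanced	positive	no_call
S13	case	advanced	positive	monosomy 18
S14	control	control	positive	low_risk
S15	control	control	positive	low_risk
S16	case	early	negative	low_risk
S17	case	early	negative	low_risk
S18	case	early	negative	low_risk
S19	case	early	negative	low_risk
S20	case	early	negative	low_risk
S21	case	early	negative	low_risk
S22	case	early	negative	low_risk
S23	case	early	negative	low_risk
S24	case	early	negative	low_risk
S25	case	early	negative	low_risk
S26	case	advanced	negative	low_risk
S27	case	advanced	negative	low_risk
S28	case	advanced	negative	low_risk
S29	case	advanced	negative	low_risk
S30	case	advanced	negative	low_risk
S31	case	advanced	negative	low_risk
S32	case	advanced	negative	low_risk
S33	case	advanced	negative	low_risk
S34	case	advanced	negative	low_risk
S35	control	control	negative	no_call
S36	control	control	negative	monosomy X
S37	control	control	negative	monosomy X
S38	control	control	negative	low_risk
S39	control	control	negative	low_risk
S40	control	control	negative	low_risk
S41	control	control	negative	low_risk
S42	control	control	negative	low_risk
S43	control	control	negative	low_risk
S44	control	control	negative	low_risk
S45	control	control	negative	low_risk
S46	control	control	negative	low_risk
S47	control	control	negative	low_risk
S48	control	control	negative	low_risk
S49	control	control	negative	low_risk
S50	control	control	negative	low_risk
S51	control	control	negative	low_risk
S52	control	control	negative	low_risk
S53	control	control	negative	low_risk
S54	control	control	negative	low_risk
S55	control	control	negative	low_risk
S56	control	control	negative	low_risk
S57	control	control	negative	low_risk
S58	control	control	negative	low_risk
S59	control	control	negative	low_risk
S60	control	control	negative	low_risk
S61	control	control	negative	low_risk
S62	control	control	negative	low_risk
S63	control	control	negative	low_risk
S64	control	control	negative	low_risk
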