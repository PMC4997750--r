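subject_id	group	stage_label	arm	direction
S01	case	early	3q	gain
S01	case	early	12p	gain
S01	case	early	20q	gain
S01	case	early	5p	gain
S01	case	early	5q	loss
S01	case	early	8p	loss
S01	case	early	9p	loss
S01	case	early	7q	loss
S02	case	early	3q	gain
S02	case	early	20	gain
S02	case	early	6p	gain
S02	case	early	2q	gain
S02	case	early	18q	gain
S02	case	early	4q	loss
S02	case	early	7p	loss
S02	case	early	13q	loss
S02	case	early	15q	loss
S03	case	early	12p	gain
S04	case	early	3q	gain
S04	case	early	8q	gain
S05	case	early	8q	gain
S05	case	early	3p	gain
S06	case	early	8q	gain
S07	case	advanced	3q	gain
S07	case	advanced	8	gain
S07	case	advanced	5p	gain
S07	case	advanced	9p	gain
S07	case	advanced	5q	loss
S07	case	advanced	13	loss
S07	case	advanced	15	loss
S07	case	advanced	17	loss
S07	case	advanced	18	loss
S07	case	advanced	22	loss
S07	case	advanced	14	loss
S08	case	advanced	8q	gain
S08	case	advanced	1q	gain
S08	case	advanced	6p	gain
S08	case	advanced	1p	gain
S08	case	advanced	11q	gain
S08	case	advanced	8p	loss
S09	case	advanced	20	gain
S10	case	advanced	11q	gain
S11	case	advanced	8q	gain
S11	case	advanced	12p	gain
S11	case	advanced	6p	gain
S11	case	advanced	7q	gain
S11	case	advanced	1p	gain
S11	case	advanced	2	gain
S11	case	advanced	5p	gain
S11	case	advanced	11q	gain
S11	case	advanced	18q	gain
S11	case	advanced	4q	loss
S11	case	advanced	5q	loss
S11	case	advanced	6q	loss
S11	case	advanced	8p	loss
S11	case	advanced	9p	loss
S11	case	advanced	13	loss
S11	case	advanced	15	loss
S11	case	advanced	17q	loss
S11	case	advanced	22	loss
S11	case	advanced	1p	loss
S11	case	advanced	10p	loss
S11	case	advanced	11q	loss
S11	case	advanced	21	loss
S12	case	advanced	3q	gain
S12	case	advanced	1q	gain
S12	case	advanced	6p	gain
S12	case	advanced	7q	gain
S12	case	advanced	10p	gain
S12	case	advanced	18	gain
S12	case	advanced	4p	loss
S12	case	advanced	9q	loss
S12	case	advanced	13	loss
S12	case	advanced	11p	loss
S12	case	advanced	5p	loss
S12	case	advanced	7p	loss
S13	case	advanced	20q	gain
S13	case	advanced	8q	gain
S14	control	control	20q	gain
S15	control	control	20q	gain
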