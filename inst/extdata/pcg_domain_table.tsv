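#name	coords	length_kb	nc_state	fc_state	s2_state
NC1	2L:2198000..2209000	11	PcG	Inactive	Active
NC2	2R:22673000..22692000	19	PcG	Inactive	Active
NC3	3L:17950000..18070000	120	PcG	Active/inactive	Active
NC4	3R:18415000..18455000	40	PcG	Active	Active
NC5	3R:18910000..18927000	17	PcG	Active	Active
NCFC1	3R:15985000..16041000	56	PcG	PcG	Active
NCFC2	3R:30750000..30782000	32	PcG/active	PcG	Active
FC1	X:5048000..5070000	22	Active	PcG	Active
FC2	X:5312000..5317000	5	Active/inactive	PcG	Active/inactive
FC3	X:19532000..19559000	27	Inactive	PcG	Active
FC4	3L:13390000..13411000	21	Inactive	PcG	Inactive
FC5	3R:23286000..23314000	28	Inactive	PcG	Active
S2FC1	2R:15658000..15676000	18	Active/inactive	PcG	Active/PcG
S2NC1	2L:6531500..6553500	22	Inactive	Active	PcG
S2NC3	2R:14307000..14322000	15	Inactive	Active	PcG
S2NC4	2R:20092500..20117500	25	Inactive	Active	PcG
S2NC2	2R:23566000..23580000	14	Inactive	Active	PcG
S2NC5	3L:607500..628000	20.5	Inactive	Active	PcG
S2NC6	3R:31689500..31712000	22.5	Inactive	Active	PcG
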