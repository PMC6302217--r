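marker_id	description
SCG001	synthetic single-copy marker placeholder
SCG002	synthetic single-copy marker placeholder
SCG003	synthetic single-copy marker placeholder
SCG004	synthetic single-copy marker placeholder
SCG005	synthetic single-copy marker placeholder
SCG006	synthetic single-copy marker placeholder
SCG007	synthetic single-copy marker placeholder
SCG008	synthetic single-copy marker placeholder
SCG009	synthetic single-copy marker placeholder
SCG010	synthetic single-copy marker placeholder
SCG011	synthetic single-copy marker placeholder
SCG012	synthetic single-copy marker placeholder
SCG013	synthetic single-copy marker placeholder
SCG014	synthetic single-copy marker placeholder
SCG015	synthetic single-copy marker placeholder
SCG016	synthetic single-copy marker placeholder
SCG017	synthetic single-copy marker placeholder
SCG018	synthetic single-copy marker placeholder
SCG019	synthetic single-copy marker placeholder
SCG020	synthetic single-copy marker placeholder
SCG021	synthetic single-copy marker placeholder
SCG022	synthetic single-copy marker placeholder
SCG023	synthetic single-copy marker placeholder
SCG024	synthetic single-copy marker placeholder
SCG025	synthetic single-copy marker placeholder
SCG026	synthetic single-copy marker placeholder
SCG027	synthetic single-copy marker placeholder
SCG028	synthetic single-copy marker placeholder
SCG029	synthetic single-copy marker placeholder
SCG030	synthetic single-copy marker placeholder
SCG031	synthetic single-copy marker placeholder
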