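marker_id	description
ESS001	synthetic essential marker placeholder
ESS002	synthetic essential marker placeholder
ESS003	synthetic essential marker placeholder
ESS004	synthetic essential marker placeholder
ESS005	synthetic essential marker placeholder
ESS006	synthetic essential marker placeholder
ESS007	synthetic essential marker placeholder
ESS008	synthetic essential marker placeholder
ESS009	synthetic essential marker placeholder
ESS010	synthetic essential marker placeholder
ESS011	synthetic essential marker placeholder
ESS012	synthetic essential marker placeholder
ESS013	synthetic essential marker placeholder
ESS014	synthetic essential marker placeholder
ESS015	synthetic essential marker placeholder
ESS016	synthetic essential marker placeholder
ESS017	synthetic essential marker placeholder
ESS018	synthetic essential marker placeholder
ESS019	synthetic essential marker placeholder
ESS020	synthetic essential marker placeholder
ESS021	synthetic essential marker placeholder
ESS022	synthetic essential marker placeholder
ESS023	synthetic essential marker placeholder
ESS024	synthetic essential marker placeholder
ESS025	synthetic essential marker placeholder
ESS026	synthetic essential marker placeholder
ESS027	synthetic essential marker placeholder
ESS028	synthetic essential marker placeholder
ESS029	synthetic essential marker placeholder
ESS030	synthetic essential marker placeholder
ESS031	synthetic essential marker placeholder
ESS032	synthetic essential marker placeholder
ESS033	synthetic essential marker placeholder
ESS034	synthetic essential marker placeholder
ESS035	synthetic essential marker placeholder
ESS036	synthetic essential marker placeholder
ESS037	synthetic essential marker placeholder
ESS038	synthetic essential marker placeholder
ESS039	synthetic essential marker placeholder
ESS040	synthetic essential marker placeholder
ESS041	synthetic essential marker placeholder
ESS042	synthetic essential marker placeholder
ESS043	synthetic essential marker placeholder
ESS044	synthetic essential marker placeholder
ESS045	synthetic essential marker placeholder
ESS046	synthetic essential marker placeholder
ESS047	synthetic essential marker placeholder
ESS048	synthetic essential marker placeholder
ESS049	synthetic essential marker placeholder
ESS050	synthetic essential marker placeholder
ESS051	synthetic essential marker placeholder
ESS052	synthetic essential marker placeholder
ESS053	synthetic essential marker placeholder
ESS054	synthetic essential marker placeholder
ESS055	synthetic essential marker placeholder
ESS056	synthetic essential marker placeholder
ESS057	synthetic essential marker placeholder
ESS058	synthetic essential marker placeholder
ESS059	synthetic essential marker placeholder
ESS060	synthetic essential marker placeholder
ESS061	synthetic essential marker placeholder
ESS062	synthetic essential marker placeholder
ESS063	synthetic essential marker placeholder
ESS064	synthetic essential marker placeholder
ESS065	synthetic essential marker placeholder
ESS066	synthetic essential marker placeholder
ESS067	synthetic essential marker placeholder
ESS068	synthetic essential marker placeholder
ESS069	synthetic essential marker placeholder
ESS070	synthetic essential marker placeholder
ESS071	synthetic essential marker placeholder
ESS072	synthetic essential marker placeholder
ESS073	synthetic essential marker placeholder
ESS074	synthetic essential marker placeholder
ESS075	synthetic essential marker placeholder
ESS076	synthetic essential marker placeholder
ESS077	synthetic essential marker placeholder
ESS078	synthetic essential marker placeholder
ESS079	synthetic essential marker placeholder
ESS080	synthetic essential marker placeholder
ESS081	synthetic essential marker placeholder
ESS082	synthetic essential marker placeholder
ESS083	synthetic essential marker placeholder
ESS084	synthetic essential marker placeholder
ESS085	synthetic essential marker placeholder
ESS086	synthetic essential marker placeholder
ESS087	synthetic essential marker placeholder
ESS088	synthetic essential marker placeholder
ESS089	synthetic essential marker placeholder
ESS090	synthetic essential marker placeholder
ESS091	synthetic essential marker placeholder
ESS092	synthetic essential marker placeholder
ESS093	synthetic essential marker placeholder
ESS094	synthetic essential marker placeholder
ESS095	synthetic essential marker placeholder
ESS096	synthetic essential marker placeholder
ESS097	synthetic essential marker placeholder
ESS098	synthetic essential marker placeholder
ESS099	synthetic essential marker placeholder
ESS100	synthetic essential marker placeholder
ESS101	synthetic essential marker placeholder
ESS102	synthetic essential marker placeholder
ESS103	synthetic essential marker placeholder
ESS104	synthetic essential marker placeholder
ESS105	synthetic essential marker placeholder
ESS106	synthetic essential marker placeholder
ESS107	synthetic essential marker placeholder
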