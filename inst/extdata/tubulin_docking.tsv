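name	lbe_mean	lbe_sd	pki_mean	pki_sd	pki_unit	site	pharmacophore
Colchicine	-7.01	0.14	0.007	0.01	mM	colchicine-site	a:LEU248;a:LYS254;a:LYS352;b:GLN11;b:ASN101;b:GLY142;b:GLY143;b:GLY144;b:THR145;b:GLU183;b:ASN206;b:TYR224
Lupeol	-4.48	0.08	0.520	0.07	mM	colchicine-site	a:LEU248;a:LYS254;a:LYS352;b:GLN11;b:GLU71;b:ASP98;b:ALA99;b:ALA100;b:ASN101;b:GLY142;b:GLY143;b:GLY144;b:THR145;b:THR179;b:GLU183
Quercetin	-4.72	0.15	0.352	0.08	mM	colchicine-site	a:GLN247;a:LEU248;a:LYS254;a:LYS352;b:GLN11;b:ALA12;b:ASP69;b:GLU71;b:ALA99;b:ALA100;b:ASN101;b:GLY144;b:THR145;b:THR179;b:ALA180
Paclitaxel	-7.37	0.25	0.004	0.01	mM	paclitaxel-site	a:LEU217;a:HIS229;a:LEU230;a:ALA233;a:SER236;a:PHE272;a:ALA273;a:PRO274;a:LEU275;a:THR276;a:SER277;a:ARG278;a:ARG320;a:PRO360;a:ARG369;a:LEU371
Lupeol	-7.12	0.01	0.006	0.01	mM	paclitaxel-site	a:THR276;a:GLN281;a:ARG284;a:LEU286;a:LEU371;a:LYS372
Quercetin	-5.99	0.29	0.045	0.02	mM	paclitaxel-site	a:LEU217;a:PRO274;a:LEU275;a:THR276;a:SER277;a:ARG278;a:GLN281;a:LEU286;a:LEU371;a:LYS372
Vincristine	-8.42	0.15	0.001	0.01	mM	vincristine-site	a:GLN11;a:CYS12;a:GLN15;a:ASN101;a:SER140;a:GLY142;a:GLY143;a:VAL172;a:PRO173;a:SER174;a:ASP179;a:THR180;a:ASN206;a:TYR224;a:ASN228
Lupeol	-8.62	0.04	0.001	0.01	mM	vincristine-site	a:GLY10;a:GLY11;a:SER140;a:GLY142;a:GLY143;a:VAL171;a:VAL172;a:PRO173;a:SER174;a:VAL177;a:ASP179;a:GLU183;a:ASN206;a:TYR210;a:TYR224
Quercetin	-6.77	0.06	0.011	0.01	mM	vincristine-site	a:CYS12;a:GLN15;a:GLY142;a:VAL172;a:PRO173;a:SER174;a:VAL177;a:ASP179;a:GLU183;a:ASN206;a:GLU207
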