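category	region	habitat	comparison	main_result	grade	reference	footnotes
disturbed_resprouting	Brazil	Grassland	2 shrub and 3 tree species	Shrubs regained more basal area and height than trees after fire/cutting	++	Hermann et al.
disturbed_resprouting	Brazil	Forest-grassland ecotone	38 shrub and 42 larger woody species	Shorter multi-stemmed shrubs dominated early regrowth after fire	+	Muller et al.
disturbed_resprouting	Brazil	Savanna (Cerrado)	4 shrubs/subshrubs and 3 tree species	Diameter growth; basal area, biomass, and heights not given	+/-	Hoffmann and Solbrig	a
disturbed_resprouting	Sweden	Mixed forest with Quercus	1 shrub and 13 tree species	Shrubs had higher growth rate and survival rate than trees after partial cutting	+	Leonardsson and Gotmark
disturbed_resprouting	Japan	Mixed forest with Quercus and Carpinus	7 shrub and 24 larger woody species	Shrubs had stronger resprouting than the other species	+	Shibata et al.
disturbed_seeders	Mexico	Tropical deciduous forest	47 species; mix, but more trees than shrubs	Shrubs and trees did not differ in height growth after clear-cut and burn	+/-	Miller and Kauffman	b
lab_experiment	Lab	Species from British isles and northern Spain	25 shrub/sub-shrub and 55 tree species	Shrubs had higher relative growth rate than trees (only tested up to day 21)	+	Cornelissen et al.
lab_experiment	Lab	The tropics; meta-analysis of 15 studies	17 shrub, 12 intermediate and 61 tree species	Shrubs accumulated more biomass than trees after nutrient addition (P < 0.07)	+	Lawrence	c
lab_experiment	Lab	Karst habitats, SW China	2 shrub and 4 tree species	Shrubs had higher biomass increase than most of the trees	+	Liu et al.	d
field_experiment	Mexico	Tropical oak forest: open, edge, and interior habitat	2 shrub and 3 tree species (seedlings planted)	Shrubs had higher biomass growth, larger root systems, and higher survival than trees	++	Asbjornsen et al.	d
field_experiment	Spain, highlands	Forest, shrub-land and open	4 shrub and 4 tree species (seeds sown)	Shrubs tended to survive better than trees, especially under dry conditions	+	Matias et al.	d,e
natural_colonization	USA, New York state	Abandoned fields	2 shrub and 2 tree species	Shrubs emerged better per seed, survived better, grew better, and became taller than the trees	++	Gardescu and Marks
other	Lab, and experiments (also herbs)	Diverse conditions	9 studies of shrubs, 27 studies of trees	Shrubs had higher median relative growth rate than trees	+	Houghton et al.	f
other	Australia	Post-fire successional habitat	17 shrub-like, 2 taller tree-like species	Shrub-like outpaced tree-like species in height growth (early growth)	+	Falster and Westoby
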