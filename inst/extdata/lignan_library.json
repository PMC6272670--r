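{
  "library_version": "1.0",
  "description": "25 constituents of Caulis Trachelospermi: 14 quantified dibenzylbutyrolactone lignan standards (1-14), tanegoside A (17), and 10 further constituents detected by HPLC-QTOF-MS. Ring tags select diagnostic benzyl-cation masses; sugars are listed in the order they are lost from the precursor.",
  "compounds": [
    {"id": 1,  "name": "nortrachelogenin 5'-C-β-D-glucoside", "formula": "C26H32O12", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "guaiacyl", "sugars": [{"residue": "Glc", "linkage": "C"}]},
    {"id": 2,  "name": "nortracheloside", "formula": "C26H32O12", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "guaiacyl", "sugars": [{"residue": "Glc", "linkage": "O"}]},
    {"id": 3,  "name": "nortrachelogenin 8'-O-β-D-glucoside", "formula": "C26H32O12", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "guaiacyl", "sugars": [{"residue": "Glc", "linkage": "O"}]},
    {"id": 4,  "name": "matairesinol 4'-O-β-gentiobioside", "formula": "C32H42O16", "subclass": "lignano-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "guaiacyl", "sugars": [{"residue": "Glc", "linkage": "O"}, {"residue": "Glc", "linkage": "O"}]},
    {"id": 5,  "name": "trachelogenin 4'-O-β-gentiobioside", "formula": "C33H44O17", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "veratryl", "sugars": [{"residue": "Glc", "linkage": "O"}, {"residue": "Glc", "linkage": "O"}]},
    {"id": 6,  "name": "matairesinoside", "formula": "C26H32O11", "subclass": "lignano-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "guaiacyl", "sugars": [{"residue": "Glc", "linkage": "O"}]},
    {"id": 7,  "name": "tracheloside", "formula": "C27H34O12", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "veratryl", "sugars": [{"residue": "Glc", "linkage": "O"}]},
    {"id": 8,  "name": "arctigenin 4'-O-β-gentiobioside", "formula": "C33H44O16", "subclass": "lignano-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "veratryl", "sugars": [{"residue": "Glc", "linkage": "O"}, {"residue": "Glc", "linkage": "O"}]},
    {"id": 9,  "name": "nortrachelogenin", "formula": "C20H22O7", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "guaiacyl", "sugars": []},
    {"id": 10, "name": "arctiin", "formula": "C27H34O11", "subclass": "lignano-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "veratryl", "sugars": [{"residue": "Glc", "linkage": "O"}]},
    {"id": 11, "name": "matairesinol", "formula": "C20H22O6", "subclass": "lignano-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "guaiacyl", "sugars": []},
    {"id": 12, "name": "trachelogenin", "formula": "C21H24O7", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "veratryl", "sugars": []},
    {"id": 13, "name": "5-methoxytrachelogenin", "formula": "C22H26O8", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "methoxy-veratryl", "sugars": []},
    {"id": 14, "name": "arctigenin", "formula": "C21H24O6", "subclass": "lignano-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "veratryl", "sugars": []},
    {"id": 15, "name": "bergenin", "formula": "C14H16O9", "subclass": "other", "ring_A": "none", "ring_Aprime": "none", "sugars": [{"residue": "Glc", "linkage": "C"}]},
    {"id": 16, "name": "kelampayoside A", "formula": "C20H30O13", "subclass": "other", "ring_A": "none", "ring_Aprime": "none", "sugars": [{"residue": "Api", "linkage": "O"}, {"residue": "Glc", "linkage": "O"}]},
    {"id": 17, "name": "tanegoside A", "formula": "C26H34O12", "subclass": "lignano-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "guaiacyl", "sugars": [{"residue": "Glc", "linkage": "O"}]},
    {"id": 18, "name": "nortrachelogenin 4,4'-di-O-β-D-glucoside", "formula": "C32H42O17", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "guaiacyl", "sugars": [{"residue": "Glc", "linkage": "O"}, {"residue": "Glc", "linkage": "O"}]},
    {"id": 19, "name": "matairesinol 4,4'-di-O-β-D-glucoside", "formula": "C32H42O16", "subclass": "lignano-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "guaiacyl", "sugars": [{"residue": "Glc", "linkage": "O"}, {"residue": "Glc", "linkage": "O"}]},
    {"id": 20, "name": "nortrachelogenin 4'-O-β-gentiobioside", "formula": "C32H42O17", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "guaiacyl", "sugars": [{"residue": "Glc", "linkage": "O"}, {"residue": "Glc", "linkage": "O"}]},
    {"id": 21, "name": "nortrachelogenin 4-O-β-D-glucoside", "formula": "C26H32O12", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "guaiacyl", "sugars": [{"residue": "Glc", "linkage": "O"}]},
    {"id": 22, "name": "4-demethyltraxillaside", "formula": "C27H34O12", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "veratryl", "sugars": [{"residue": "Glc", "linkage": "O"}]},
    {"id": 23, "name": "dihydrodehydrodiconiferyl alcohol-9-O-β-D-glucoside", "formula": "C26H34O11", "subclass": "other", "ring_A": "none", "ring_Aprime": "none", "sugars": [{"residue": "Glc", "linkage": "O"}]},
    {"id": 24, "name": "traxillageside", "formula": "C28H36O12", "subclass": "lignano-8'-hydroxy-9,9'-lactone", "ring_A": "guaiacyl", "ring_Aprime": "methoxy-veratryl", "sugars": [{"residue": "Glc", "linkage": "O"}]},
    {"id": 25, "name": "apigenin 7-O-β-neospheroside", "formula": "C27H30O14", "subclass": "other", "ring_A": "none", "ring_Aprime": "none", "sugars": [{"residue": "Rha", "linkage": "O"}, {"residue": "Glc", "linkage": "O"}]}
  ]
}
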