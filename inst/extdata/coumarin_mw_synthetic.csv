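# Synthetic fixture: molecular weights of the twelve APR coumarins and the
# two marker compounds, derived by the package authors from molecular
# formulas (not transcribed from any assay report). Angepubebisin's formula
# is an informed estimate for a bis-coumarin and is approximate.
compound_id,name,formula,mw
1,umbelliferone,C9H6O3,162.14
2,osthol,C15H16O3,244.29
3,scopoletin,C10H8O4,192.17
4,peucedanol,C14H18O4,250.29
5,ulopterol,C15H20O4,264.32
6,angepubebisin,C26H26O8,466.48
7,psoralen,C11H6O3,186.16
8,xanthotoxin,C12H8O4,216.19
9,bergapten,C12H8O4,216.19
10,isoimperatorin,C16H14O4,270.28
11,columbianadin,C19H20O5,328.36
12,columbianetin acetate,C16H16O5,288.30
caffeine,caffeine,C8H10N4O2,194.19
atenolol,atenolol,C14H22N2O3,266.34
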