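A	C	G	T
-1.13750352374993	-3.4594316186373	-3.4594316186373	1.75002174699165
-3.4594316186373	-3.4594316186373	-3.4594316186373	1.89812038598079
-3.4594316186373	-3.4594316186373	-3.4594316186373	1.89812038598079
-3.4594316186373	-1.13750352374993	-3.4594316186373	1.75002174699165
1.89812038598079	-3.4594316186373	-3.4594316186373	-3.4594316186373
-3.4594316186373	-1.13750352374993	-3.4594316186373	1.75002174699165
-3.4594316186373	-3.4594316186373	1.89812038598079	-3.4594316186373
-3.4594316186373	-3.4594316186373	-3.4594316186373	1.89812038598079
-3.4594316186373	-1.13750352374993	-3.4594316186373	1.75002174699165
-3.4594316186373	-3.4594316186373	-3.4594316186373	1.89812038598079
1.75002174699165	-3.4594316186373	-1.13750352374993	-3.4594316186373
-3.4594316186373	-3.4594316186373	1.89812038598079	-3.4594316186373
-1.13750352374993	-3.4594316186373	-3.4594316186373	1.75002174699165
-3.4594316186373	-3.4594316186373	-3.4594316186373	1.89812038598079
-3.4594316186373	-3.4594316186373	-3.4594316186373	1.89812038598079
-3.4594316186373	-3.4594316186373	-3.4594316186373	1.89812038598079
1.75002174699165	-3.4594316186373	-3.4594316186373	-1.13750352374993
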