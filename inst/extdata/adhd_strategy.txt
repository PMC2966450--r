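1 Attention Deficit Disorder with Hyperactivity/
2 adhd
3 addh
4 adhs
5 hyperactiv$
6 hyperkin$
7 attention deficit$
8 brain dysfunction
9 or/1-8
10 Child/
11 Adolescent/
12 child$ or boy$ or girl$ or schoolchild$ or adolescen$ or teen$ or "young person$" or "young people$" or youth$
13 or/10-12
14 acupuncture therapy/or acupuncture, ear/or electroacupuncture/
15 accupunct$
16 or/14-15
17 9 and 13 and 16
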