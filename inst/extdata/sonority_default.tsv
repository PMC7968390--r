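# Default letter sonority table (symbol <TAB> rank, 1..10).
# 10-rank hierarchy from open vowels (10) down to voiceless stops (1);
# letters outside the printed hierarchy carry ranks based on their usual
# pronunciation (c, q as /k/; x, h fricative-like; y as the glide).
# Edit and load with read_sonority_table() to override.
a	10
e	9
o	9
i	8
u	8
j	8
w	8
r	7
l	6
m	5
n	5
z	4
v	4
f	3
s	3
b	2
d	2
g	2
p	1
t	1
k	1
c	1
q	1
x	3
y	8
h	3
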