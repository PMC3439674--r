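# Default French stop-word list (normalized: lowercase, unaccented).
# ~120 common function words; a deployment should supply its own fuller list.
le
la
les
l
un
une
des
de
du
d
au
aux
a
et
ou
mais
donc
or
ni
car
ne
pas
plus
moins
tres
peu
trop
si
que
qu
qui
quoi
dont
quand
comme
comment
pourquoi
parce
avec
sans
sous
sur
dans
en
entre
vers
par
pour
chez
avant
apres
pendant
depuis
contre
selon
mon
ma
mes
ton
ta
tes
son
sa
ses
notre
nos
votre
vos
leur
leurs
ce
cet
cette
ces
cela
ca
celui
celle
ceux
celles
je
tu
il
elle
on
nous
vous
ils
elles
me
te
se
soi
moi
toi
lui
eux
y
est
sont
etre
avoir
ai
as
ont
suis
es
sommes
etes
etait
etaient
fut
sera
seront
the
of
and
when
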