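raw_text,target
20/10,20/10
20/20,20/20
20/25,20/25
20/30,20/30
20/40,20/40
20/50,20/50
20/60,20/60
20/70,20/70
20/80,20/80
20/100,20/100
20/125,20/125
20/200,20/200
20/400,20/400
cf,CF
counting fingers,CF
count fingers,CF
cf (counting fingers),CF
hm,HM
hand motion,HM
hand motions,HM
hm (hand motion),HM
lp,LP
light perception,LP
lp (light perception),LP
nlp,NLP
no light perception,NLP
nlp (no light perception),NLP
j1,NEAR
j1+,NEAR
j2,NEAR
j3,NEAR
j4,NEAR
j5,NEAR
j6,NEAR
j7,NEAR
j8,NEAR
j9,NEAR
j10,NEAR
j11,NEAR
j12,NEAR
j13,NEAR
j14,NEAR
j15,NEAR
j16,NEAR
font 8,NEAR
font 10,NEAR
font 12,NEAR
print 8,NEAR
print 10,NEAR
print 12,NEAR
not tested,UNMAPPED
nt,UNMAPPED
unable,UNMAPPED
unable to test,UNMAPPED
unable to assess,UNMAPPED
ni,UNMAPPED
no improvement,UNMAPPED
deferred,UNMAPPED
declined,UNMAPPED
poor view,UNMAPPED
no view,UNMAPPED
eyes closed,UNMAPPED
prosthesis,UNMAPPED
enucleated,UNMAPPED
see above,UNMAPPED
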