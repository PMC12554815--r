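# synthetic stand-in for the published stretching-band table:
# polymer bands vs droplet-relevant reference absorbers
# intensity unit: a.u. (opaque source units)
molecule,wavenumber,intensity
polymer,1459.46650878293,450
polymer,1185.86735743936,450
polymer,1004.15051162615,450
polymer,896.948057269212,450
polymer,845,500
polymer,861,500
polymer,757,180
polymer,601,60
polymer,524,140
h2so4,3609,150
h2so4,1452,450
h2so4,1216,380
h2so4,1157,250
h2so4,891,350
h2so4,550,60
h3po4,3673,120
h3po4,1178,420
h3po4,1008,380
h3po4,890,340
h3po4,520,40
so3,1391,520
so3,1065,20
so3,529,90
so2,1362,400
so2,1151,320
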