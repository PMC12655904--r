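letter,name,description
a,AverageMass,Average mass
c,HBondDonors,Number of H-bond donors
d,Density,Density
e,LUMO,LUMO energy
f,FreelyRotatingBonds,Number of freely rotating bonds
g,HBondAcceptors,Number of H-bond acceptors
h,FukuiMax,Maximum positive Fukui index
i,PolarSurfaceArea,Polar surface area
j,HOMO,HOMO energy
k,LogD,LogD (pH 7.4)
s,SurfaceTension,Surface tension
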