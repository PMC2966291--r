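# Simplified InChI grammar: version prefix, formula layer, and the
# connectivity (/c) and hydrogen (/h) layers as opaque token sequences.
# The full InChI specification is out of scope.
inchi <- header
inchi <- header layers
header <- pfx fsl formula
pfx <- 'InChI=1S' 'InChI=1'
fsl <- '/'
formula <- funit
formula <- funit formula
funit <- felem
funit <- felem num
num <- fdigit
num <- fdigit num
layers <- layer
layers <- layer layers
layer <- cmark ctoks
layer <- hmark htoks
cmark <- '/c'
hmark <- '/h'
ctoks <- ctok
ctoks <- ctok ctoks
ctok <- fdigit
ctok <- punct
htoks <- htok
htoks <- htok htoks
htok <- fdigit
htok <- punct
htok <- felem
felem <- 'Cl' 'Br' 'Si' 'Na' 'C' 'H' 'N' 'O' 'P' 'S' 'F' 'I' 'K'
fdigit <- '0' '1' '2' '3' '4' '5' '6' '7' '8' '9'
punct <- '-' ',' '(' ')'
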