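# Practical SMILES grammar: organic-subset elements and their aromatic
# lowercase forms, bond symbols, ring-closure digits, nested branches, and
# bracket atoms with optional isotope, chirality, hydrogen count and charge.
# The digit class is shared between ring closures, isotopes, hydrogen counts
# and charge magnitudes; '-' is shared between bonds and negative charges.
smiles <- chain
chain <- bunit
chain <- bunit chain
chain <- bunit bond chain
bunit <- atom
bunit <- atom posts
atom <- organic
atom <- aromatic
atom <- bracket
posts <- post
posts <- post posts
post <- ring
post <- branch
ring <- digit
branch <- '(' bchain ')'
bchain <- chain
bchain <- bond chain
bond <- bondsym
bond <- dash
bracket <- '[' belem ']'
bracket <- '[' isotope belem ']'
isotope <- num
num <- digit
num <- digit num
belem <- esym
belem <- esym mods
esym <- organic
esym <- aromatic
esym <- hsym
esym <- element
mods <- mod
mods <- mod mods
mod <- chiral
mod <- hcount
mod <- charge
chiral <- chiralsym
hcount <- hsym
hcount <- hsym digit
charge <- plus
charge <- plus digit
charge <- dash
charge <- dash digit
organic <- 'Cl' 'Br' 'B' 'C' 'N' 'O' 'P' 'S' 'F' 'I'
aromatic <- 'b' 'c' 'n' 'o' 'p' 's'
bondsym <- '=' '#' '/' '\\'
dash <- '-'
digit <- '0' '1' '2' '3' '4' '5' '6' '7' '8' '9'
chiralsym <- '@@' '@'
hsym <- 'H'
plus <- '+'
# note: two-character element tokens must not be the concatenation of two
# shorter tokens, or greedy longest-match lexing would re-read sampler
# output (e.g. 'S'+'n' as tin, 'P'+'b' as lead); such elements are omitted
element <- 'Si' 'Se' 'As' 'Na' 'K' 'Li' 'Ca' 'Fe' 'Zn' 'Mg' 'Al' 'Hg'
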