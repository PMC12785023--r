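name	formula	class
dCTP	C9H16N3O13P3	nucleotide
dATP	C10H16N5O12P3	nucleotide
dGTP	C10H16N5O13P3	nucleotide
dTTP	C10H17N2O14P3	nucleotide
ATP	C10H16N5O13P3	nucleotide
ADP	C10H15N5O10P2	nucleotide
AMP	C10H14N5O7P	nucleotide
GTP	C10H16N5O14P3	nucleotide
CTP	C9H16N3O14P3	nucleotide
UTP	C9H15N2O15P3	nucleotide
NAD	C21H27N7O14P2	nucleotide
FAD	C27H33N9O15P2	nucleotide
glucose	C6H12O6	sugar
sucrose	C12H22O11	sugar
ribose	C5H10O5	sugar
lactate	C3H6O3	organic acid
pyruvate	C3H4O3	organic acid
citrate	C6H8O7	organic acid
succinate	C4H6O4	organic acid
glutathione	C10H17N3O6S	peptide
glutamine	C5H10N2O3	amino acid
taurine	C2H7NO3S	amino acid derivative
creatine	C4H9N3O2	amino acid derivative
palmitic acid	C16H32O2	fatty acid
oleic acid	C18H34O2	fatty acid
stearic acid	C18H36O2	fatty acid
arachidonic acid	C20H32O2	fatty acid
PI(38:4)	C47H83O13P	glycerophospholipid
PS(36:1)	C42H82NO10P	glycerophospholipid
PE(38:4)	C43H78NO8P	glycerophospholipid
PC(34:1)	C42H82NO8P	glycerophospholipid
PG(34:1)	C40H77O10P	glycerophospholipid
PA(36:2)	C39H73O8P	glycerophospholipid
SM(d34:1)	C39H79N2O6P	sphingolipid
cholesterol	C27H46O	sterol
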