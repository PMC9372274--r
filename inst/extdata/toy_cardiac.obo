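format-version: 1.2
ontology: toy-cardiac
remark: Synthetic miniature cardiovascular phenotype ontology shipped as a package fixture. Term ids use a reserved HP:9xxxxxx block and do NOT correspond to real Human Phenotype Ontology accessions; names echo common congenital heart disease vocabulary so examples read naturally.

[Term]
id: HP:9000001
name: Abnormality of the cardiovascular system

[Term]
id: HP:9000010
name: Abnormal heart morphology
is_a: HP:9000001

[Term]
id: HP:9000020
name: Abnormal great vessel morphology
is_a: HP:9000001

[Term]
id: HP:9000030
name: Abnormal heart valve morphology
is_a: HP:9000010

[Term]
id: HP:9000040
name: Abnormal cardiac conduction
is_a: HP:9000001

[Term]
id: HP:9000011
name: Abnormal cardiac septum morphology
is_a: HP:9000010

[Term]
id: HP:9000012
name: Abnormal ventricular morphology
is_a: HP:9000010

[Term]
id: HP:9000013
name: Abnormal cardiac position
is_a: HP:9000010

[Term]
id: HP:9000014
name: Abnormal atrioventricular connection
is_a: HP:9000010

[Term]
id: HP:9000015
name: Abnormal atrial morphology
is_a: HP:9000010

[Term]
id: HP:9000031
name: Abnormal atrioventricular valve morphology
is_a: HP:9000030

[Term]
id: HP:9000032
name: Abnormal tricuspid valve morphology
is_a: HP:9000031

[Term]
id: HP:9000033
name: Abnormal mitral valve morphology
is_a: HP:9000031

[Term]
id: HP:9000101
name: Ventricular septal defect
alt_id: HP:9000901
is_a: HP:9000011

[Term]
id: HP:9000102
name: Atrial septal defect
is_a: HP:9000011

[Term]
id: HP:9000103
name: Patent foramen ovale
is_a: HP:9000011

[Term]
id: HP:9000104
name: Common atrium
is_a: HP:9000015

[Term]
id: HP:9000105
name: Right ventricular hypertrophy
is_a: HP:9000012

[Term]
id: HP:9000106
name: Single ventricle
is_a: HP:9000012

[Term]
id: HP:9000107
name: Hypoplastic right heart
is_a: HP:9000012

[Term]
id: HP:9000108
name: Tetralogy of Fallot
is_a: HP:9000012
is_a: HP:9000020

[Term]
id: HP:9000109
name: Dextrocardia
is_a: HP:9000013

[Term]
id: HP:9000110
name: Mesocardia
is_a: HP:9000013

[Term]
id: HP:9000111
name: Atrioventricular canal defect
is_a: HP:9000011
is_a: HP:9000014

[Term]
id: HP:9000201
name: Patent ductus arteriosus
is_a: HP:9000020

[Term]
id: HP:9000202
name: Aortopulmonary collateral arteries
is_a: HP:9000020

[Term]
id: HP:9000203
name: Pulmonary artery atresia
is_a: HP:9000020

[Term]
id: HP:9000204
name: Pulmonary artery stenosis
is_a: HP:9000020

[Term]
id: HP:9000205
name: Right aortic arch
is_a: HP:9000020

[Term]
id: HP:9000206
name: Persistent left superior vena cava
is_a: HP:9000020

[Term]
id: HP:9000207
name: Transposition of the great arteries
is_a: HP:9000020

[Term]
id: HP:9000208
name: Abnormal aortic morphology
is_a: HP:9000020

[Term]
id: HP:9000301
name: Tricuspid regurgitation
is_a: HP:9000032

[Term]
id: HP:9000302
name: Tricuspid stenosis
is_a: HP:9000032

[Term]
id: HP:9000303
name: Tricuspid atresia
is_a: HP:9000032

[Term]
id: HP:9000304
name: Mitral atresia
is_a: HP:9000033

[Term]
id: HP:9000401
name: Right bundle branch block
is_a: HP:9000040

[Term]
id: HP:9000402
name: Abnormal T-wave
is_a: HP:9000040

[Term]
id: HP:9000998
name: obsolete Cardiomegaly variant
is_obsolete: true
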