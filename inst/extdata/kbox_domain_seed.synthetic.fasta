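>kbox_synthetic_seed01
ESLERQLDSSLKQIRSRKNQLLLDQLQELQRKEHALAEANRQLRRKLEESGQELPLQLNPNQQEAADMGF
>kbox_synthetic_seed02
ECLETQLDSSLKQIRSYKNQGLLDGLQEHQRKEHALAEANRQLRRKLERSGHELPLQLNPNQQYLADMGF
>kbox_synthetic_seed03
EMLESQLTSSLKQIRSRKNQLLLFQLQELQRKEHALAEANFQMRRKLHESGQEQPLQLVPNQQEAADMGT
>kbox_synthetic_seed04
EKLERQLDSSLKQARSRKNQLHLDQLQELQRKEHALAEWNAQLRVKLEESGQELLLQHNPNQQKAADMKF
>kbox_synthetic_seed05
WSLERQLDSSLKQISSRKNQLLLDQLQELIRKEHFLAEANRQLERILADSGQELPLQLNPNQQECAWMGF
>kbox_synthetic_seed06
ESLERHLDSSLKQIRSRKNVLLLDQLPELQRIEFALAEANDRLRRKCEESGQELPLQENPNQQEAAMMGF
>kbox_synthetic_seed07
ESLERQLMSSLKQIRSRKNQFGLDQLQGLQRKEGALAEANRPLRRKFEEPGQELPLQLNPVQQEKADMGF
>kbox_synthetic_seed08
ESLERSLDSSHKQIRSRKNQLLLDQLQELQRKPHNKTEANRQLSRKLEESGQEWPLQLNPWQQEAADMGQ
>kbox_synthetic_seed09
ESLEKQDDSCLKQIRSDKNQRFLRQLQELLRKEHALAEANRQERRKLEESGQELYLQLNPNQQEAADMGF
>kbox_synthetic_seed10
ESLERQLDSSQKQIRQWKNVLLLDQLQELQRKEHALAEANRQRMRKMEELGQELPLMLNPNQEEAADMGF
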