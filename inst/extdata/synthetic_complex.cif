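data_syn1
_entry.id SYN1

_pdbx_database_status.entry_id SYN1
_pdbx_database_status.recvd_initial_deposition_date 2000-01-01

_cell.entry_id SYN1
_cell.length_a 1
_cell.length_b 1
_cell.length_c 1
_cell.angle_alpha 90
_cell.angle_beta 90
_cell.angle_gamma 90

_symmetry.entry_id SYN1
_symmetry.space_group_name_H-M ''

loop_
_entity.id
_entity.type
A polymer
B polymer

loop_
_entity_poly.entity_id
_entity_poly.type
_entity_poly.pdbx_strand_id
_entity_poly.pdbx_seq_one_letter_code
A polypeptide(L) A ?
B polyribonucleotide B ?



loop_
_chem_comp.id
_chem_comp.type
A .
ALA .
ASN .
ASP .
C .
CYS .
G .
GLN .
GLY .
HIS .
ILE .
LEU .
LYS .
MET .
PHE .
PRO .
SER .
THR .
TRP .
TYR .
U .
VAL .

loop_
_exptl.entry_id
_exptl.method
SYN1 'X-RAY DIFFRACTION'

_struct_keywords.entry_id SYN1
_struct_keywords.pdbx_keywords 'SYNTHETIC RNA-PROTEIN COMPLEX'

loop_
_struct_asym.id
_struct_asym.entity_id
Axp A
Bxp B



loop_
_atom_type.symbol
C
N
P


loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_formal_charge
_atom_site.auth_seq_id
_atom_site.auth_asym_id
_atom_site.pdbx_PDB_model_num
ATOM 1 C CA . HIS Axp A . ? 6 20 0 1 0 ? 1 A 1
ATOM 2 C CB . HIS Axp A . ? 6 21 0 1 0 ? 1 A 1
ATOM 3 C CA . TRP Axp A . ? 12 20 0 1 0 ? 2 A 1
ATOM 4 C CB . TRP Axp A . ? 12 21 0 1 0 ? 2 A 1
ATOM 5 C CA . ILE Axp A . ? 18 20 0 1 0 ? 3 A 1
ATOM 6 C CB . ILE Axp A . ? 18 5.617 0 1 0 ? 3 A 1
ATOM 7 C CA . CYS Axp A . ? 24 20 0 1 0 ? 4 A 1
ATOM 8 C CB . CYS Axp A . ? 24 21 0 1 0 ? 4 A 1
ATOM 9 C CA . ASP Axp A . ? 30 20 0 1 0 ? 5 A 1
ATOM 10 C CB . ASP Axp A . ? 30 21 0 1 0 ? 5 A 1
ATOM 11 C CA . LEU Axp A . ? 36 20 0 1 0 ? 6 A 1
ATOM 12 C CB . LEU Axp A . ? 36 21 0 1 0 ? 6 A 1
ATOM 13 C CA . LYS Axp A . ? 42 20 0 1 0 ? 7 A 1
ATOM 14 C CB . LYS Axp A . ? 42 6.157 0 1 0 ? 7 A 1
ATOM 15 C CA . TYR Axp A . ? 48 20 0 1 0 ? 8 A 1
ATOM 16 C CB . TYR Axp A . ? 48 21 0 1 0 ? 8 A 1
ATOM 17 C CA . LYS Axp A . ? 54 20 0 1 0 ? 9 A 1
ATOM 18 C CB . LYS Axp A . ? 54 21 0 1 0 ? 9 A 1
ATOM 19 C CA . ILE Axp A . ? 60 20 0 1 0 ? 10 A 1
ATOM 20 C CB . ILE Axp A . ? 60 21 0 1 0 ? 10 A 1
ATOM 21 C CA . THR Axp A . ? 66 20 0 1 0 ? 11 A 1
ATOM 22 C CB . THR Axp A . ? 66 21 0 1 0 ? 11 A 1
ATOM 23 C CA . ILE Axp A . ? 72 20 0 1 0 ? 12 A 1
ATOM 24 C CB . ILE Axp A . ? 72 21 0 1 0 ? 12 A 1
ATOM 25 C CA . PRO Axp A . ? 78 20 0 1 0 ? 13 A 1
ATOM 26 C CB . PRO Axp A . ? 78 21 0 1 0 ? 13 A 1
ATOM 27 C CA . ALA Axp A . ? 84 20 0 1 0 ? 14 A 1
ATOM 28 C CB . ALA Axp A . ? 84 21 0 1 0 ? 14 A 1
ATOM 29 C CA . PHE Axp A . ? 90 20 0 1 0 ? 15 A 1
ATOM 30 C CB . PHE Axp A . ? 90 21 0 1 0 ? 15 A 1
ATOM 31 C CA . SER Axp A . ? 96 20 0 1 0 ? 16 A 1
ATOM 32 C CB . SER Axp A . ? 96 21 0 1 0 ? 16 A 1
ATOM 33 C CA . ASN Axp A . ? 102 20 0 1 0 ? 17 A 1
ATOM 34 C CB . ASN Axp A . ? 102 21 0 1 0 ? 17 A 1
ATOM 35 C CA . ILE Axp A . ? 108 20 0 1 0 ? 18 A 1
ATOM 36 C CB . ILE Axp A . ? 108 21 0 1 0 ? 18 A 1
ATOM 37 C CA . VAL Axp A . ? 114 20 0 1 0 ? 19 A 1
ATOM 38 C CB . VAL Axp A . ? 114 21 0 1 0 ? 19 A 1
ATOM 39 C CA . THR Axp A . ? 120 20 0 1 0 ? 20 A 1
ATOM 40 C CB . THR Axp A . ? 120 21 0 1 0 ? 20 A 1
ATOM 41 C CA . ASN Axp A . ? 126 20 0 1 0 ? 21 A 1
ATOM 42 C CB . ASN Axp A . ? 126 21 0 1 0 ? 21 A 1
ATOM 43 C CA . MET Axp A . ? 132 20 0 1 0 ? 22 A 1
ATOM 44 C CB . MET Axp A . ? 132 21 0 1 0 ? 22 A 1
ATOM 45 C CA . PHE Axp A . ? 138 20 0 1 0 ? 23 A 1
ATOM 46 C CB . PHE Axp A . ? 138 21 0 1 0 ? 23 A 1
ATOM 47 C CA . VAL Axp A . ? 144 20 0 1 0 ? 24 A 1
ATOM 48 C CB . VAL Axp A . ? 144 21 0 1 0 ? 24 A 1
ATOM 49 C CA . ALA Axp A . ? 150 20 0 1 0 ? 25 A 1
ATOM 50 C CB . ALA Axp A . ? 150 21 0 1 0 ? 25 A 1
ATOM 51 C CA . PHE Axp A . ? 156 20 0 1 0 ? 26 A 1
ATOM 52 C CB . PHE Axp A . ? 156 21 0 1 0 ? 26 A 1
ATOM 53 C CA . TYR Axp A . ? 162 20 0 1 0 ? 27 A 1
ATOM 54 C CB . TYR Axp A . ? 162 21 0 1 0 ? 27 A 1
ATOM 55 C CA . MET Axp A . ? 168 20 0 1 0 ? 28 A 1
ATOM 56 C CB . MET Axp A . ? 168 21 0 1 0 ? 28 A 1
ATOM 57 C CA . GLN Axp A . ? 174 20 0 1 0 ? 29 A 1
ATOM 58 C CB . GLN Axp A . ? 174 21 0 1 0 ? 29 A 1
ATOM 59 C CA . GLY Axp A . ? 180 20 0 1 0 ? 30 A 1
ATOM 60 C CB . GLY Axp A . ? 180 21 0 1 0 ? 30 A 1
ATOM 61 P P . C Bxp B . ? 6 0 0 1 0 ? 1 B 1
ATOM 62 N N1 . C Bxp B . ? 6 1.5 0 1 0 ? 1 B 1
ATOM 63 P P . C Bxp B . ? 12 0 0 1 0 ? 2 B 1
ATOM 64 N N1 . C Bxp B . ? 12 1.5 0 1 0 ? 2 B 1
ATOM 65 P P . C Bxp B . ? 18 0 0 1 0 ? 3 B 1
ATOM 66 N N1 . C Bxp B . ? 18 1.5 0 1 0 ? 3 B 1
ATOM 67 P P . G Bxp B . ? 24 0 0 1 0 ? 4 B 1
ATOM 68 N N1 . G Bxp B . ? 24 1.5 0 1 0 ? 4 B 1
ATOM 69 P P . A Bxp B . ? 30 0 0 1 0 ? 5 B 1
ATOM 70 N N1 . A Bxp B . ? 30 1.5 0 1 0 ? 5 B 1
ATOM 71 P P . A Bxp B . ? 36 0 0 1 0 ? 6 B 1
ATOM 72 N N1 . A Bxp B . ? 36 1.5 0 1 0 ? 6 B 1
ATOM 73 P P . G Bxp B . ? 42 0 0 1 0 ? 7 B 1
ATOM 74 N N1 . G Bxp B . ? 42 1.5 0 1 0 ? 7 B 1
ATOM 75 P P . U Bxp B . ? 48 0 0 1 0 ? 8 B 1
ATOM 76 N N1 . U Bxp B . ? 48 1.5 0 1 0 ? 8 B 1
ATOM 77 P P . C Bxp B . ? 54 0 0 1 0 ? 9 B 1
ATOM 78 N N1 . C Bxp B . ? 54 1.5 0 1 0 ? 9 B 1
ATOM 79 P P . G Bxp B . ? 60 0 0 1 0 ? 10 B 1
ATOM 80 N N1 . G Bxp B . ? 60 1.5 0 1 0 ? 10 B 1
ATOM 81 P P . A Bxp B . ? 66 0 0 1 0 ? 11 B 1
ATOM 82 N N1 . A Bxp B . ? 66 1.5 0 1 0 ? 11 B 1
ATOM 83 P P . C Bxp B . ? 72 0 0 1 0 ? 12 B 1
ATOM 84 N N1 . C Bxp B . ? 72 1.5 0 1 0 ? 12 B 1
ATOM 85 P P . C Bxp B . ? 78 0 0 1 0 ? 13 B 1
ATOM 86 N N1 . C Bxp B . ? 78 1.5 0 1 0 ? 13 B 1
ATOM 87 P P . G Bxp B . ? 84 0 0 1 0 ? 14 B 1
ATOM 88 N N1 . G Bxp B . ? 84 1.5 0 1 0 ? 14 B 1
ATOM 89 P P . A Bxp B . ? 90 0 0 1 0 ? 15 B 1
ATOM 90 N N1 . A Bxp B . ? 90 1.5 0 1 0 ? 15 B 1
ATOM 91 P P . C Bxp B . ? 96 0 0 1 0 ? 16 B 1
ATOM 92 N N1 . C Bxp B . ? 96 1.5 0 1 0 ? 16 B 1
ATOM 93 P P . U Bxp B . ? 102 0 0 1 0 ? 17 B 1
ATOM 94 N N1 . U Bxp B . ? 102 1.5 0 1 0 ? 17 B 1
ATOM 95 P P . G Bxp B . ? 108 0 0 1 0 ? 18 B 1
ATOM 96 N N1 . G Bxp B . ? 108 1.5 0 1 0 ? 18 B 1
ATOM 97 P P . G Bxp B . ? 114 0 0 1 0 ? 19 B 1
ATOM 98 N N1 . G Bxp B . ? 114 1.5 0 1 0 ? 19 B 1
ATOM 99 P P . C Bxp B . ? 120 0 0 1 0 ? 20 B 1
ATOM 100 N N1 . C Bxp B . ? 120 1.5 0 1 0 ? 20 B 1
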