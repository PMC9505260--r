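data_toy_pocket
_entry.id 'toy_pocket'

_cell.entry_id 'toy_pocket'
_cell.length_a 1
_cell.length_b 1
_cell.length_c 1
_cell.angle_alpha 90
_cell.angle_beta 90
_cell.angle_gamma 90

_symmetry.entry_id 'toy_pocket'
_symmetry.space_group_name_H-M ''

loop_
_entity.id
_entity.type
1 polymer

loop_
_entity_poly.entity_id
_entity_poly.type
_entity_poly.pdbx_strand_id
_entity_poly.pdbx_seq_one_letter_code
1 polypeptide(L) A ?



loop_
_chem_comp.id
_chem_comp.type
ALA .
ARG .
GLU .

loop_
_struct_asym.id
_struct_asym.entity_id
Axp 1



loop_
_atom_type.symbol
C
N
O


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
ATOM 1 N N . ALA Axp 1 . ? -2.559 7.193 -0.7 1 60 ? 228 A 1
ATOM 2 C CA . ALA Axp 1 . ? -1.359 6.693 0 1 60 ? 228 A 1
ATOM 3 C C . ALA Axp 1 . ? -0.159 7.293 0.6 1 60 ? 228 A 1
ATOM 4 O O . ALA Axp 1 . ? -0.059 8.493 0.8 1 60 ? 228 A 1
ATOM 5 C CB . ALA Axp 1 . ? -1.658 8.163 0 1 60 ? 228 A 1
ATOM 6 N N . ARG Axp 1 . ? -9.2 -3.633 -0.7 1 60 ? 578 A 1
ATOM 7 C CA . ARG Axp 1 . ? -8 -4.133 0 1 60 ? 578 A 1
ATOM 8 C C . ARG Axp 1 . ? -6.8 -3.533 0.6 1 60 ? 578 A 1
ATOM 9 O O . ARG Axp 1 . ? -6.7 -2.333 0.8 1 60 ? 578 A 1
ATOM 10 C CB . ARG Axp 1 . ? -6.543 -4.001 0 1 60 ? 578 A 1
ATOM 11 C CG . ARG Axp 1 . ? -5.202 -3.678 0 1 60 ? 578 A 1
ATOM 12 C CD . ARG Axp 1 . ? -3.922 -3.763 0 1 60 ? 578 A 1
ATOM 13 N NE . ARG Axp 1 . ? -2.677 -3.45 0 1 60 ? 578 A 1
ATOM 14 C CZ . ARG Axp 1 . ? -1.98 -3.587 0 1 60 ? 578 A 1
ATOM 15 N NH1 . ARG Axp 1 . ? -0.859 -2.984 0 1 60 ? 578 A 1
ATOM 16 N NH2 . ARG Axp 1 . ? -0.769 -3.98 0 1 60 ? 578 A 1
ATOM 17 N N . GLU Axp 1 . ? 8.159 -2.06 -0.7 1 60 ? 629 A 1
ATOM 18 C CA . GLU Axp 1 . ? 9.359 -2.56 0 1 60 ? 629 A 1
ATOM 19 C C . GLU Axp 1 . ? 10.559 -1.96 0.6 1 60 ? 629 A 1
ATOM 20 O O . GLU Axp 1 . ? 10.659 -0.76 0.8 1 60 ? 629 A 1
ATOM 21 C CB . GLU Axp 1 . ? 7.325 -2.745 0 1 60 ? 629 A 1
ATOM 22 C CG . GLU Axp 1 . ? 5.409 -2.717 0 1 60 ? 629 A 1
ATOM 23 C CD . GLU Axp 1 . ? 3.665 -3.076 0 1 60 ? 629 A 1
ATOM 24 O OE1 . GLU Axp 1 . ? 2.128 -2.713 0 1 60 ? 629 A 1
ATOM 25 O OE2 . GLU Axp 1 . ? 2.219 -3.709 0 1 60 ? 629 A 1
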