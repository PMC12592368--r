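data_structure
#
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.auth_atom_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_seq_id
_atom_site.label_alt_id
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.pdbx_PDB_model_num
ATOM 1 N N ASP A 101 . 13.540 0.000 0.000 1.00 1
ATOM 2 C CA ASP A 101 . 15.000 0.000 0.000 1.00 1
ATOM 3 C C ASP A 101 . 15.520 1.430 0.000 1.00 1
ATOM 4 O O ASP A 101 . 15.950 2.580 0.000 1.00 1
ATOM 5 C CB ASP A 101 . 15.510 -0.510 1.340 1.00 1
ATOM 6 C CG ASP A 101 . 16.012 -1.012 2.684 1.00 1
ATOM 7 O OD1 ASP A 101 . 17.112 -1.012 3.234 1.00 1
ATOM 8 O OD2 ASP A 101 . 14.912 -1.012 3.234 1.00 1
ATOM 9 N N GLU A 102 . 13.540 0.000 11.500 1.00 1
ATOM 10 C CA GLU A 102 . 15.000 0.000 11.500 1.00 1
ATOM 11 C C GLU A 102 . 15.520 1.430 11.500 1.00 1
ATOM 12 O O GLU A 102 . 15.950 2.580 11.500 1.00 1
ATOM 13 C CB GLU A 102 . 15.510 -0.510 12.840 1.00 1
ATOM 14 C CG GLU A 102 . 16.012 -1.012 14.184 1.00 1
ATOM 15 C CD GLU A 102 . 16.514 -1.514 15.528 1.00 1
ATOM 16 O OE1 GLU A 102 . 17.614 -1.514 16.078 1.00 1
ATOM 17 O OE2 GLU A 102 . 15.414 -1.514 16.078 1.00 1
#
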