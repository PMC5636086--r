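protein,pdb_start,pdb_end,n_residues,rmsd,resolution
T4 lysozyme,178L,256L,162,3.4,1.80
Maltodextrin binding protein,1OMP,1ANF,370,3.8,1.67
D-allose binding protein,1GUD,1RPJ,288,4.5,1.70
LAO binding protein,2LAO,1LST,238,4.7,1.80
5'-nucleotidase,1OID,1OI8,525,5.5,2.10
Ribose-binding protein,1BA2,2DRI,271,6.2,1.60
Adenylate kinase,4AKE,1AKE,214,7.1,2.00
Ribonuclease III,1YZ9,1YYO,438,7.3,2.10
Group II chaperonin,3IYF,3J03,3928,15.4,4.80
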