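begin model
begin molecule types
  Nephrin(y1,y2,y3)
  Nck(sh2,sh3a,sh3b,sh3c)
  NWASP(p1,p2,p3,p4,p5,p6)
end molecule types
begin seed species
  Nephrin(y1,y2,y3) 180
  Nck(sh2,sh3a,sh3b,sh3c) 540
  NWASP(p1,p2,p3,p4,p5,p6) 270
end seed species
begin reaction rules
  neph_y1_nck_sh2: Nephrin(y1) + Nck(sh2) <-> Nephrin(y1!1).Nck(sh2!1) 0.1, 0.01
  neph_y2_nck_sh2: Nephrin(y2) + Nck(sh2) <-> Nephrin(y2!1).Nck(sh2!1) 0.1, 0.01
  neph_y3_nck_sh2: Nephrin(y3) + Nck(sh2) <-> Nephrin(y3!1).Nck(sh2!1) 0.1, 0.01
  nck_sh3a_nwasp_p1: Nck(sh3a) + NWASP(p1) <-> Nck(sh3a!1).NWASP(p1!1) 0.1, 0.01
  nck_sh3a_nwasp_p2: Nck(sh3a) + NWASP(p2) <-> Nck(sh3a!1).NWASP(p2!1) 0.1, 0.01
  nck_sh3a_nwasp_p3: Nck(sh3a) + NWASP(p3) <-> Nck(sh3a!1).NWASP(p3!1) 0.1, 0.01
  nck_sh3a_nwasp_p4: Nck(sh3a) + NWASP(p4) <-> Nck(sh3a!1).NWASP(p4!1) 0.1, 0.01
  nck_sh3a_nwasp_p5: Nck(sh3a) + NWASP(p5) <-> Nck(sh3a!1).NWASP(p5!1) 0.1, 0.01
  nck_sh3a_nwasp_p6: Nck(sh3a) + NWASP(p6) <-> Nck(sh3a!1).NWASP(p6!1) 0.1, 0.01
  nck_sh3b_nwasp_p1: Nck(sh3b) + NWASP(p1) <-> Nck(sh3b!1).NWASP(p1!1) 0.1, 0.01
  nck_sh3b_nwasp_p2: Nck(sh3b) + NWASP(p2) <-> Nck(sh3b!1).NWASP(p2!1) 0.1, 0.01
  nck_sh3b_nwasp_p3: Nck(sh3b) + NWASP(p3) <-> Nck(sh3b!1).NWASP(p3!1) 0.1, 0.01
  nck_sh3b_nwasp_p4: Nck(sh3b) + NWASP(p4) <-> Nck(sh3b!1).NWASP(p4!1) 0.1, 0.01
  nck_sh3b_nwasp_p5: Nck(sh3b) + NWASP(p5) <-> Nck(sh3b!1).NWASP(p5!1) 0.1, 0.01
  nck_sh3b_nwasp_p6: Nck(sh3b) + NWASP(p6) <-> Nck(sh3b!1).NWASP(p6!1) 0.1, 0.01
  nck_sh3c_nwasp_p1: Nck(sh3c) + NWASP(p1) <-> Nck(sh3c!1).NWASP(p1!1) 0.1, 0.01
  nck_sh3c_nwasp_p2: Nck(sh3c) + NWASP(p2) <-> Nck(sh3c!1).NWASP(p2!1) 0.1, 0.01
  nck_sh3c_nwasp_p3: Nck(sh3c) + NWASP(p3) <-> Nck(sh3c!1).NWASP(p3!1) 0.1, 0.01
  nck_sh3c_nwasp_p4: Nck(sh3c) + NWASP(p4) <-> Nck(sh3c!1).NWASP(p4!1) 0.1, 0.01
  nck_sh3c_nwasp_p5: Nck(sh3c) + NWASP(p5) <-> Nck(sh3c!1).NWASP(p5!1) 0.1, 0.01
  nck_sh3c_nwasp_p6: Nck(sh3c) + NWASP(p6) <-> Nck(sh3c!1).NWASP(p6!1) 0.1, 0.01
end reaction rules
begin observables
  free_molecule Nephrin_free Nephrin
  free_molecule Nck_free Nck
  free_molecule NWASP_free NWASP
  total_clusters clusters
end observables
end model
simulate t_end=10 n_steps=20 n_runs=10 seed=1
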