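"record_id","gcs_total","intubated","pupils","midline_shift_mm","temporal_pathology","edh_width_mm","operative","exclusion_reason","age_years","transport_minutes","mechanism"
"SIM00001",9,0,"normal",1.7,1,0,0,"none",29.3,83.7,"mvc"
"SIM00002",6,0,"normal",3.6,0,0,0,"none",56.8,44.9,"fall"
"SIM00003",10,0,"normal",2.3,1,0,0,"none",28.2,66,"mvc"
"SIM00004",6,0,"normal",4.6,1,0,0,"none",18,40.3,"mvc"
"SIM00005",10,1,"unilateral_enlarged",1.1,0,0,0,"none",42.3,85.8,"mvc"
"SIM00006",4,1,"normal",4.8,1,0,0,"none",64.1,47.6,"mvc"
"SIM00007",4,0,"normal",1,0,0,0,"none",49.6,61.1,"bicycle"
"SIM00008",11,0,"normal",8.4,0,0,1,"none",49.6,43.1,"pedestrian"
"SIM00009",5,1,"normal",0.1,1,0,0,"none",21,36.5,"pedestrian"
"SIM00010",10,0,"normal",1.7,1,0,0,"none",38.9,23.6,"assault"
"SIM00011",4,1,"normal",1.5,0,0,0,"none",37.9,22.3,"pedestrian"
"SIM00012",11,1,"normal",3.7,0,0,0,"none",28.9,80.7,"assault"
"SIM00013",5,0,"normal",4.2,0,0,0,"none",25.2,81.6,"pedestrian"
"SIM00014",8,0,"unilateral_enlarged",9.4,1,0,1,"none",51.2,55.8,"fall"
"SIM00015",8,0,"normal",1.5,0,18.9,0,"none",34.5,96.3,"mvc"
"SIM00016",12,0,"normal",4.3,0,0,0,"none",36.7,55.7,"pedestrian"
"SIM00017",12,1,"normal",4.7,1,16.6,0,"none",29.4,109.9,"fall"
"SIM00018",12,0,"unilateral_enlarged",2,0,0,0,"none",53,45.7,"bicycle"
"SIM00019",7,0,"normal",1.1,1,0,0,"none",64.3,94.7,"mvc"
"SIM00020",8,0,"normal",0.1,1,11.2,1,"none",40.6,55.2,"assault"
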