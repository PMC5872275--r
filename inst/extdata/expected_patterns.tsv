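assay	mellifera_H1	mellifera_H2	carpatica	carnica	caucasica
AmEu1	107,32	139	139	139	139
AmEu2	150	122,28	150	150	150
AmCarp	141	141	111,30	111,30	141
AmCar	148	148	148	118,30	148
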