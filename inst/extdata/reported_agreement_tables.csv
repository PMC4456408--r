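table,measure,group,mean_a,sd_a,mean_b,sd_b,r,bias,sd_diff
GCC,RNFL,normal,36.5,4.2,37.7,4.3,0.86,-1.1,1.8
GCC,GCL+IPL,normal,69.3,5.1,71.3,4.8,0.91,-2.0,2.0
GCC,RNFL+GCL+IPL,normal,105.8,7.7,108.9,7.3,0.90,-3.1,2.6
GCC,RNFL,glaucoma,26.7,9.5,30.4,6.4,0.78,-3.7,6.4
GCC,GCL+IPL,glaucoma,61.2,7.5,59.2,11.2,0.83,2.0,6.7
GCC,RNFL+GCL+IPL,glaucoma,87.0,16.2,89.5,16.4,0.90,-2.5,7.6
ETDRS,Cen,normal,223.6,18.5,217.3,17.8,0.95,6.3,5.9
ETDRS,Sin,normal,299.7,17.0,296.5,17.2,0.96,3.2,4.5
ETDRS,Nin,normal,300.9,18.0,296.7,17.4,0.93,4.2,6.5
ETDRS,Iin,normal,295.7,17.0,293.7,16.4,0.94,2.1,5.7
ETDRS,Tin,normal,284.0,16.5,283.6,16.3,0.95,0.4,5.3
ETDRS,Sout,normal,265.7,15.0,262.8,15.5,0.94,2.8,5.5
ETDRS,Nout,normal,281.8,16.6,284.3,21.3,0.86,-2.5,11.4
ETDRS,Iout,normal,254.0,14.2,251.6,15.2,0.90,2.5,6.7
ETDRS,Tout,normal,249.7,14.5,246.2,15.4,0.79,3.6,9.7
ETDRS,Ave,normal,268.9,13.5,267.0,14.1,0.96,1.9,4.0
ETDRS,Cen,glaucoma,225.1,21.6,216.8,20.0,0.84,8.3,11.8
ETDRS,Sin,glaucoma,284.7,22.4,281.7,22.7,0.93,3.0,8.7
ETDRS,Nin,glaucoma,285.2,23.2,283.0,23.8,0.90,2.2,11.0
ETDRS,Iin,glaucoma,276.5,25.1,275.2,24.3,0.95,1.3,7.8
ETDRS,Tin,glaucoma,269.1,21.3,267.0,21.4,0.91,2.1,8.9
ETDRS,Sout,glaucoma,246.5,20.3,245.3,20.1,0.93,1.2,7.8
ETDRS,Nout,glaucoma,263.2,22.9,263.4,26.2,0.71,-0.2,19.0
ETDRS,Iout,glaucoma,235.5,21.2,232.1,20.8,0.92,3.4,5.6
ETDRS,Tout,glaucoma,234.3,19.1,234.9,22.1,0.70,-0.6,16.2
ETDRS,Ave,glaucoma,251.4,18.6,250.7,19.0,0.93,1.0,7.4
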